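# Y-lineage tools: haplogroup assignment on a SNP-labelled reference tree,
# ASD and SNP-accumulation TMRCA dating, and stepwise haplotype distances.

#' Construct a haplogroup reference tree
#'
#' Wraps a rooted `ape` phylogeny whose tip and internal labels are
#' haplogroup names, optionally with a table of branch-defining SNPs. Each
#' SNP belongs to exactly one branch, identified by the label of the node
#' at the branch's child end.
#'
#' @param phylo an `ape` `phylo` object (rooted; unique labels). Internal
#'   nodes without labels are auto-labelled `node_<k>`.
#' @param snps optional data frame with columns `snp_id`, `branch`,
#'   `ancestral`, `derived`.
#' @return An object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(phylo, snps = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(phylo$node.label) || !length(phylo$node.label)) {
    phylo$node.label <- sprintf("node_%d", seq_len(phylo$Nnode))
  }
  empty <- !nzchar(phylo$node.label) | is.na(phylo$node.label)
  phylo$node.label[empty] <- sprintf("node_%d", which(empty))
  labs <- c(phylo$tip.label, phylo$node.label)
  if (anyDuplicated(labs)) {
    stop("tree labels must be unique: ", paste(labs[duplicated(labs)], collapse = ", "))
  }
  if (!is.null(snps)) {
    need <- c("snp_id", "branch", "ancestral", "derived")
    if (!all(need %in% names(snps))) {
      stop("snps must have columns ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(snps$snp_id)) stop("each SNP must map to exactly one branch")
    bad <- setdiff(snps$branch, labs)
    if (length(bad)) stop("SNP branches not in tree: ", paste(bad, collapse = ", "))
  }
  out <- list(phylo = phylo, snps = snps)
  class(out) <- "haplogroup_tree"
  out
}

as_haplogroup_tree <- function(x) {
  if (inherits(x, "haplogroup_tree")) x else haplogroup_tree(x)
}

#' Read a haplogroup tree from a Newick file
#'
#' @param path Newick file.
#' @param snps optional branch-SNP table (see [haplogroup_tree()]), or a
#'   path to a TSV with the same columns.
#' @return A `haplogroup_tree`.
#' @export
read_haplogroup_tree <- function(path, snps = NULL) {
  if (is.character(snps) && length(snps) == 1L) {
    snps <- read.table(snps, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  haplogroup_tree(ape::read.tree(path), snps)
}

root_to_tip_path <- function(phy, tip_index) {
  ape::nodepath(phy, length(phy$tip.label) + 1L, tip_index)
}

#' Assign a Y haplogroup from SNP genotypes
#'
#' Scores every root-to-tip path of the reference tree by its genotype
#' support (number of derived calls minus number of ancestral calls at the
#' path's branch-defining SNPs) and returns the deepest branch carrying a
#' derived call on the best-supported path. Ties between paths are broken
#' by the larger number of derived calls, then by lexicographically smaller
#' assigned label. Derived calls on branches off the chosen path are
#' conflicts and are counted, not silently dropped. All-ancestral genotypes
#' yield the root label.
#'
#' @param genotypes named character vector of allele calls (names = SNP
#'   ids; `NA` = missing). Alleles are matched against the tree's
#'   ancestral/derived allele columns.
#' @param htree a [haplogroup_tree()] with a `snps` table.
#' @return A list of class `haplogroup_call`: `haplogroup`, `score`,
#'   `n_derived_path`, `n_conflicts`, `tip` (the supporting tip),
#'   `n_callable`.
#' @export
assign_haplogroup <- function(genotypes, htree) {
  stopifnot(inherits(htree, "haplogroup_tree"))
  snps <- htree$snps
  if (is.null(snps)) stop("reference tree carries no branch-defining SNPs")
  phy <- htree$phylo
  labs <- c(phy$tip.label, phy$node.label)
  root_label <- phy$node.label[1]

  g <- genotypes[snps$snp_id]
  state <- rep(NA_character_, nrow(snps))
  state[!is.na(g) & g == snps$derived] <- "derived"
  state[!is.na(g) & g == snps$ancestral] <- "ancestral"
  if (!any(!is.na(state))) {
    stop("no callable genotypes at any tree-defining SNP")
  }

  derived_branches <- snps$branch[!is.na(state) & state == "derived"]
  ancestral_branches <- snps$branch[!is.na(state) & state == "ancestral"]

  best <- NULL
  for (tip in seq_along(phy$tip.label)) {
    path_nodes <- root_to_tip_path(phy, tip)
    path_labels <- labs[path_nodes[-1]]  # branch = child-end label; root excluded
    nd <- sum(derived_branches %in% path_labels)
    na_ <- sum(ancestral_branches %in% path_labels)
    score <- nd - na_
    # deepest branch on the path with at least one derived call
    hit <- path_labels %in% derived_branches
    label <- if (any(hit)) path_labels[max(which(hit))] else root_label
    cand <- list(score = score, nd = nd, label = label, tip = phy$tip.label[tip])
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && nd > best$nd) ||
        (score == best$score && nd == best$nd && label < best$label)) {
      best <- cand
      best$path_labels <- path_labels
    }
  }
  conflicts <- sum(!(derived_branches %in% best$path_labels))
  out <- list(haplogroup = best$label, score = best$score,
              n_derived_path = best$nd, n_conflicts = conflicts,
              tip = best$tip, n_callable = sum(!is.na(state)))
  class(out) <- "haplogroup_call"
  out
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("Haplogroup %s (path support %d derived, score %d, %d conflicting derived call%s)\n",
              x$haplogroup, x$n_derived_path, x$score, x$n_conflicts,
              if (x$n_conflicts == 1) "" else "s"))
  invisible(x)
}

#' Default 23-locus Y-STR panel with mutation rates
#'
#' The 23-locus forensic panel split into 11 slower- and 12 faster-mutating
#' loci. The per-locus, per-generation mutation probabilities are
#' literature-scale defaults for these loci (roughly 5e-4 to 1.5e-3 for the
#' slow set and 2e-3 to 7e-3 for the fast set); supply your own table when
#' calibrated rates are available.
#'
#' @return Data frame with columns `locus`, `class` (`SLOW`/`FAST`), `mu`.
#' @export
ppy23_panel <- function() {
  data.frame(
    locus = c("DYS389I", "DYS391", "DYS392", "DYS393", "DYS437", "DYS438",
              "DYS448", "DYS533", "DYS635", "DYS643", "YGATAH4",
              "DYS19", "DYS385a", "DYS385b", "DYS389II", "DYS390", "DYS439",
              "DYS456", "DYS458", "DYS481", "DYS549", "DYS570", "DYS576"),
    class = c(rep("SLOW", 11), rep("FAST", 12)),
    mu = c(0.0012, 0.0010, 0.0005, 0.0010, 0.0011, 0.0005,
           0.0014, 0.0012, 0.0012, 0.0010, 0.0013,
           0.0022, 0.0023, 0.0023, 0.0028, 0.0021, 0.0050,
           0.0042, 0.0063, 0.0050, 0.0028, 0.0070, 0.0066),
    stringsAsFactors = FALSE)
}

modal_founder <- function(haplotypes) {
  apply(haplotypes, 2, function(v) {
    v <- v[!is.na(v)]
    tab <- table(v)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    if (length(cand) > 1L) {
      d <- abs(cand - mean(v))
      cand <- cand[d == min(d)]
    }
    min(cand)
  })
}

#' ASD (average squared distance) TMRCA estimate from Y-STR haplotypes
#'
#' Founder-anchored estimator: with founder repeat `f_l` and sampled repeats
#' `a_il`, the per-locus ASD is `mean_i (a_il - f_l)^2`, which has
#' expectation `mu_l * T` generations under the single-step mutation model.
#' The point estimate is the mean of the per-locus ratios `ASD_l / mu_l`
#' and its standard error the standard deviation of those ratios divided by
#' `sqrt(L)`. The default founder is the per-locus modal repeat (ties
#' resolved towards the mean, then the smaller value). A pairwise variant
#' (`ASD` across all sample pairs divided by `2 mu_l`) is available.
#'
#' @param haplotypes integer matrix or data frame, samples x loci.
#' @param rates named numeric vector of per-locus mutation rates, or a data
#'   frame with columns `locus`, `mu`. Defaults to [ppy23_panel()].
#' @param panel `"ALL"`, `"SLOW"` or `"FAST"`; the latter two require
#'   `panel_tags`.
#' @param panel_tags named character vector (`SLOW`/`FAST`) per locus;
#'   defaults to the bundled panel classes.
#' @param gen_years years per generation (default 31).
#' @param founder optional named founder haplotype; `NULL` uses the modal
#'   founder.
#' @param estimator `"founder"` (default) or `"pairwise"`.
#' @return An object of class `tmrca_estimate` with `T_generations`,
#'   `T_years`, `SE_years`, `method`, `n_samples`, `n_loci`.
#' @export
asd_tmrca <- function(haplotypes, rates = NULL, panel = c("ALL", "SLOW", "FAST"),
                      panel_tags = NULL, gen_years = 31, founder = NULL,
                      estimator = c("founder", "pairwise")) {
  panel <- match.arg(panel)
  estimator <- match.arg(estimator)
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) < 2) stop("need at least two haplotypes")
  pp <- ppy23_panel()
  if (is.null(rates)) rates <- setNames(pp$mu, pp$locus)
  if (is.data.frame(rates)) rates <- setNames(rates$mu, rates$locus)
  if (is.null(panel_tags)) panel_tags <- setNames(pp$class, pp$locus)

  loci <- colnames(haplotypes)
  if (panel != "ALL") {
    keep <- loci[!is.na(panel_tags[loci]) & panel_tags[loci] == panel]
    haplotypes <- haplotypes[, keep, drop = FALSE]
    loci <- keep
  }
  missing_rate <- loci[!loci %in% names(rates) | !is.finite(rates[loci])]
  if (length(missing_rate)) {
    warning("excluding loci without a mutation rate: ",
            paste(missing_rate, collapse = ", "))
    loci <- setdiff(loci, missing_rate)
  }
  if (!length(loci)) stop("no loci with mutation rates remain")
  haplotypes <- haplotypes[, loci, drop = FALSE]
  mu <- rates[loci]

  if (estimator == "founder") {
    if (is.null(founder)) founder <- modal_founder(haplotypes)
    f <- as.numeric(founder[loci])
    asd <- colMeans(sweep(haplotypes, 2, f)^2, na.rm = TRUE)
    ratio <- asd / mu
  } else {
    n <- nrow(haplotypes)
    asd <- apply(haplotypes, 2, function(v) {
      v <- v[!is.na(v)]
      mean(as.numeric(dist(v))^2)
    })
    ratio <- asd / (2 * mu)
  }
  T_gen <- mean(ratio)
  se_gen <- if (length(ratio) > 1) sd(ratio) / sqrt(length(ratio)) else NA_real_
  out <- list(T_generations = T_gen, T_years = T_gen * gen_years,
              SE_years = se_gen * gen_years,
              method = paste0("ASD_", panel),
              estimator = estimator,
              n_samples = nrow(haplotypes), n_loci = length(loci),
              gen_years = gen_years)
  class(out) <- "tmrca_estimate"
  out
}

#' SNP-accumulation TMRCA estimate
#'
#' Point estimate `T = n_snps / rate` generations, with an exact 95%
#' Poisson confidence interval on the SNP count obtained from the
#' chi-square quantile relation (`lower = qchisq(.025, 2n)/2`,
#' `upper = qchisq(.975, 2(n+1))/2`), scaled by the rate and the
#' generation time.
#'
#' @param n_snps observed number of SNPs accumulated since the founder.
#' @param snps_per_generation expected SNPs per generation (> 0).
#' @param gen_years years per generation (default 31).
#' @return A `tmrca_estimate` with `CI_years` (length 2) in addition to the
#'   common fields.
#' @export
snp_tmrca <- function(n_snps, snps_per_generation, gen_years = 31) {
  n_snps <- check_count(n_snps, "n_snps", positive = FALSE)
  if (!is.numeric(snps_per_generation) || snps_per_generation <= 0) {
    stop("'snps_per_generation' must be > 0")
  }
  T_gen <- n_snps / snps_per_generation
  lo <- if (n_snps == 0) 0 else qchisq(0.025, 2 * n_snps) / 2 / snps_per_generation
  hi <- qchisq(0.975, 2 * (n_snps + 1)) / 2 / snps_per_generation
  out <- list(T_generations = T_gen, T_years = T_gen * gen_years,
              SE_years = NA_real_,
              CI_generations = c(lo, hi), CI_years = c(lo, hi) * gen_years,
              method = "SNP_COUNT", n_samples = NA_integer_, n_loci = n_snps,
              gen_years = gen_years)
  class(out) <- "tmrca_estimate"
  out
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA (%s): %.1f generations = %.0f years", x$method,
              x$T_generations, x$T_years))
  if (is.finite(x$SE_years)) cat(sprintf(" +/- %.0f", x$SE_years))
  if (!is.null(x$CI_years)) {
    cat(sprintf(" [95%% CI %.0f, %.0f]", x$CI_years[1], x$CI_years[2]))
  }
  cat("\n")
  invisible(x)
}

#' Pairwise single-step distances between Y-STR haplotypes
#'
#' `d(a, b) = sum_l |a_l - b_l|` over the loci observed in both haplotypes.
#'
#' @param haplotypes integer matrix or data frame, samples x loci.
#' @return Symmetric numeric matrix of distances.
#' @export
pairwise_step_distance <- function(haplotypes) {
  m <- as.matrix(haplotypes)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(shared)) stop(sprintf("haplotypes %d and %d share no loci", i, j))
      d[i, j] <- d[j, i] <- sum(abs(m[i, shared] - m[j, shared]))
    }
  }
  d
}
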