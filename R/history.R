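# Historical inference: minimum independent NAHR origins under irreversible
# parsimony, phylogeny-wide generation counts and per-generation NAHR rate,
# founder-expansion folds, and X-linked Hardy-Weinberg testing.

# Count minimal gains for one presence set under gain-only (irreversible)
# parsimony: the number of maximal subtrees whose tips are all present.
count_gains <- function(phy, present_tips) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  allpres <- c(phy$tip.label %in% present_tips, rep(TRUE, nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    allpres[po$edge[i, 1]] <- allpres[po$edge[i, 1]] && allpres[po$edge[i, 2]]
  }
  parent <- rep(NA_integer_, ntip + nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  gains <- which(allpres & (seq_len(ntip + nnode) == root |
                              !allpres[ifelse(is.na(parent), root, parent)]))
  # nodes above no present tip are vacuously "all present" only if childless;
  # every node has tips below it, so allpres is FALSE there and they drop out.
  labs <- c(phy$tip.label, phy$node.label)
  labs[gains]
}

#' Minimum number of independent NAHR origins
#'
#' For each junction type, presence is marked on every lineage tip carrying
#' at least one sample of that type, and the minimum number of gains under
#' irreversible (gain-only, no-loss) parsimony is the number of maximal
#' subtrees in which every tip is present. Gain-only parsimony is the right
#' model here because the same junction type observed in disjoint
#' haplogroups is evidence of recurrent formation, not of losses in the
#' lineages between them. The total is the sum over junction types.
#'
#' @param origins data frame with columns `tip` (lineage tip label) and
#'   `type_id` (junction type), one row per sample (an origin table).
#' @param tree a [haplogroup_tree()] or `phylo`.
#' @return A list: `n_origins` (total minimum gains), `per_type` (data
#'   frame `type_id`, `n_gains`), `assignments` (list of gain branch labels
#'   per type).
#' @export
min_origins <- function(origins, tree) {
  stopifnot(is.data.frame(origins), nrow(origins) > 0,
            all(c("tip", "type_id") %in% names(origins)))
  tree <- as_haplogroup_tree(tree)
  phy <- tree$phylo
  bad <- setdiff(origins$tip, phy$tip.label)
  if (length(bad)) stop("unknown lineage tips: ", paste(unique(bad), collapse = ", "))
  types <- unique(origins$type_id)
  assignments <- lapply(types, function(ty) {
    count_gains(phy, unique(origins$tip[origins$type_id == ty]))
  })
  names(assignments) <- types
  per_type <- data.frame(type_id = types,
                         n_gains = vapply(assignments, length, integer(1)),
                         row.names = NULL)
  list(n_origins = sum(per_type$n_gains), per_type = per_type,
       assignments = assignments)
}

#' Total generations in a phylogeny and the per-generation NAHR rate
#'
#' The number of root-to-tip SNPs divides the total SNP count of the
#' reference phylogeny to give the number of independent branch traversals,
#' which multiplied by the TMRCA in generations yields the total number of
#' generations contained in the phylogeny. Dividing the number of
#' independent NAHR origins by this total gives the formation rate per
#' generation. Both values are returned unrounded.
#'
#' @param S_total total SNPs in the reference phylogeny.
#' @param s_tip_mean mean number of SNPs from root to a tip clade.
#' @param tmrca_years time to the most recent common ancestor, years.
#' @param gen_years years per generation.
#' @param n_events number of independent origins (>= 0).
#' @return A list: `generations`, `rate_per_generation`.
#' @export
branch_generations_and_rate <- function(S_total, s_tip_mean, tmrca_years,
                                        gen_years, n_events) {
  if (any(c(S_total, s_tip_mean, tmrca_years, gen_years) <= 0)) {
    stop("S_total, s_tip_mean, tmrca_years and gen_years must all be positive")
  }
  if (s_tip_mean > S_total) stop("s_tip_mean cannot exceed S_total")
  if (n_events < 0) stop("n_events must be >= 0")
  generations <- (S_total / s_tip_mean) * (tmrca_years / gen_years)
  list(generations = generations, rate_per_generation = n_events / generations)
}

#' Founder-lineage expansion fold
#'
#' Ratio of the current carrier frequency to the founder-time frequency
#' (`founder_carriers / founder_pop`).
#'
#' @param current_freq current carrier frequency (proportion).
#' @param founder_carriers carriers at founding (>= 1; typically 1).
#' @param founder_pop population size at founding (> 0).
#' @return The expansion fold (numeric).
#' @export
expansion_fold <- function(current_freq, founder_carriers, founder_pop) {
  check_proportion(current_freq, "current_freq")
  if (founder_pop <= 0) stop("founder_pop must be > 0")
  if (founder_carriers < 1) stop("founder_carriers must be >= 1")
  current_freq / (founder_carriers / founder_pop)
}

#' Hardy-Weinberg test for an X-linked deletion allele
#'
#' Jointly estimates the allele frequency from hemizygous male carriers and
#' female het/hom carriers, `q = (males + het + 2 hom) / (n_males + 2
#' n_females)`, and compares the five observed cells (male carrier /
#' non-carrier; female het / hom / non-carrier) to their Hardy-Weinberg
#' expectations with a chi-square statistic on 2 degrees of freedom (five
#' cells minus two sex totals minus one estimated parameter). Expected
#' homozygote counts are typically far below 5 at rare-allele frequencies;
#' the chi-square is still reported, and a parametric-bootstrap p-value is
#' available via `mc = TRUE`.
#'
#' @param n_male_carriers,n_males hemizygous deletion males and total males.
#' @param n_het_females,n_hom_females,n_females heterozygous and homozygous
#'   deletion females and total females.
#' @param mc if `TRUE`, also compute a Monte-Carlo p-value by resampling
#'   cohorts at the estimated allele frequency.
#' @param B Monte-Carlo replicates.
#' @param seed optional seed for the Monte-Carlo p-value.
#' @return An object of class `hwe_x_test`: `q_hat`, `observed`,
#'   `expected`, `statistic`, `df`, `p.value` and optionally `p.mc`.
#' @export
hwe_x_test <- function(n_male_carriers, n_males, n_het_females, n_hom_females,
                       n_females, mc = FALSE, B = 10000, seed = NULL) {
  if (n_males <= 0 || n_females <= 0) stop("sample totals must be positive")
  if (n_male_carriers > n_males || n_het_females + n_hom_females > n_females) {
    stop("carrier counts exceed sample totals")
  }
  chi_of <- function(cm, ch, co) {
    q <- (cm + ch + 2 * co) / (n_males + 2 * n_females)
    expected <- c(male_carrier = q * n_males,
                  male_ref = (1 - q) * n_males,
                  female_het = 2 * q * (1 - q) * n_females,
                  female_hom = q^2 * n_females,
                  female_ref = (1 - q)^2 * n_females)
    observed <- c(cm, n_males - cm, ch, co, n_females - ch - co)
    list(q = q, obs = observed, exp = expected,
         chi = sum((observed - expected)^2 / expected))
  }
  fit <- chi_of(n_male_carriers, n_het_females, n_hom_females)
  out <- list(q_hat = fit$q, observed = fit$obs, expected = fit$exp,
              statistic = fit$chi, df = 2,
              p.value = pchisq(fit$chi, df = 2, lower.tail = FALSE))
  if (mc) {
    out$p.mc <- with_seed(seed, {
      q <- fit$q
      sims <- vapply(seq_len(B), function(b) {
        cm <- rbinom(1, n_males, q)
        gf <- rmultinom(1, n_females, c((1 - q)^2, 2 * q * (1 - q), q^2))
        chi_of(cm, gf[2], gf[3])$chi
      }, numeric(1))
      mean(sims >= fit$chi - 1e-12)
    })
  }
  class(out) <- "hwe_x_test"
  out
}

#' @export
print.hwe_x_test <- function(x, ...) {
  cat(sprintf("X-linked Hardy-Weinberg test: q = %.3g, chi-square = %.4g (df = %d), p = %.4g\n",
              x$q_hat, x$statistic, x$df, x$p.value))
  if (!is.null(x$p.mc)) cat(sprintf("Monte-Carlo p = %.4g\n", x$p.mc))
  invisible(x)
}
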