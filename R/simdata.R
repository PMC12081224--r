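# Synthetic-data generators: SNP-array intensity cohorts, star-genealogy
# Y-STR evolution, recombinant LTR6B junction sets, and phenotype tables.
# Every generator takes an explicit seed and returns the planted truth.

#' Specify a synthetic screening cohort
#'
#' Parameters of a simulated SNP-array cohort for the ePAR / X-deletion
#' dosage screen. Defaults reproduce the screening conditions of a large
#' biobank: ~218k males and ~264k females, an ePAR carrier frequency of
#' 0.77% among males, and an X-deletion allele frequency of 2.4e-4.
#'
#' Marker intensities are linear in copy number with additive Gaussian noise:
#' `value = copy_signal * copies + background + N(0, noise_sd)`. The
#' `background` term models non-specific hybridization and keeps zero-copy
#' intensities positive so that log2 ratios in the sex-balance filter are
#' well defined.
#'
#' @param n_males,n_females cohort sizes.
#' @param freq_epar proportion of males carrying the ePAR (2 copies of the
#'   informative interval).
#' @param freq_xdel_allele population frequency of the X-deletion allele;
#'   males are hemizygous carriers with this probability, female genotypes
#'   follow Hardy-Weinberg proportions.
#' @param n_markers_informative markers inside the 113-kb screened interval
#'   (default 60, the informative SNP count of the screening array).
#' @param n_markers_flankX,n_markers_flankY X- and Y-chromosome markers
#'   outside all PAR-associated regions, used by the sex-balance filter.
#' @param n_markers_par1 markers in proximal PAR1 (copy number 2/3/1 for
#'   reference, ePAR and deletion males); excluded from both the balance
#'   filter and the informative set.
#' @param copy_signal expected intensity increment per copy.
#' @param noise_sd per-marker Gaussian noise standard deviation.
#' @param background baseline intensity added to every marker.
#' @param aneuploidy_fraction proportion of samples given an extra X
#'   chromosome (47,XXY males / 47,XXX females), which the balance filter
#'   must exclude.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_males = 218282, n_females = 264300,
                        freq_epar = 0.0077, freq_xdel_allele = 2.4e-4,
                        n_markers_informative = 60,
                        n_markers_flankX = 20, n_markers_flankY = 20,
                        n_markers_par1 = 8,
                        copy_signal = 1, noise_sd = 0.1,
                        background = 0.4 * copy_signal,
                        aneuploidy_fraction = 0.002, seed = NULL) {
  spec <- list(
    n_males = check_count(n_males, "n_males"),
    n_females = check_count(n_females, "n_females", positive = FALSE),
    freq_epar = check_proportion(freq_epar, "freq_epar"),
    freq_xdel_allele = check_proportion(freq_xdel_allele, "freq_xdel_allele"),
    n_markers_informative = check_count(n_markers_informative, "n_markers_informative"),
    n_markers_flankX = check_count(n_markers_flankX, "n_markers_flankX"),
    n_markers_flankY = check_count(n_markers_flankY, "n_markers_flankY"),
    n_markers_par1 = check_count(n_markers_par1, "n_markers_par1"),
    copy_signal = copy_signal, noise_sd = noise_sd,
    background = background,
    aneuploidy_fraction = check_proportion(aneuploidy_fraction, "aneuploidy_fraction"),
    seed = seed)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.numeric(copy_signal) || copy_signal <= 0) stop("'copy_signal' must be > 0")
  if (freq_epar + freq_xdel_allele > 1) stop("male class frequencies exceed 1")
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a SNP-array intensity cohort with known dosage truth
#'
#' Draws per-sample dosage classes (male: reference / ePAR carrier / deletion
#' hemizygote; female: reference / heterozygous / homozygous deletion),
#' then generates marker intensities proportional to copy number plus
#' Gaussian noise. Flanking X/Y markers reflect sex-chromosome balance;
#' aneuploid samples carry an extra X on the flanking markers only.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `epar_cohort` with elements
#'   `intensities` (data frame: `sample_id`, `sex`, one column per marker),
#'   `markers` (data frame: `marker_id`, `chrom`, `pos`, `region` with
#'   regions `EPAR_INTERVAL`, `PAR1`, `X_FLANK`, `Y_FLANK`; 1-based GRCh38
#'   convention), and `truth` (data frame: `sample_id`, `sex`, `class`,
#'   `aneuploid`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_females < 1) {
    stop("cohort must contain at least one female: female reference medians are undefined otherwise")
  }
  with_seed(spec$seed, {
    nm <- spec$n_males; nf <- spec$n_females; n <- nm + nf
    sex <- c(rep("M", nm), rep("F", nf))
    q <- spec$freq_xdel_allele
    male_class <- sample(c("REF", "EPAR", "DEL_HEMI"), nm, replace = TRUE,
                         prob = c(1 - spec$freq_epar - q, spec$freq_epar, q))
    female_class <- sample(c("REF", "HET_DEL", "HOM_DEL"), nf, replace = TRUE,
                           prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    class <- c(male_class, female_class)
    aneuploid <- runif(n) < spec$aneuploidy_fraction
    sample_id <- sprintf("S%06d", seq_len(n))

    # copy numbers per region
    inf_copies <- ifelse(sex == "M",
                         c(REF = 1, EPAR = 2, DEL_HEMI = 0)[class],
                         c(REF = 2, HET_DEL = 1, HOM_DEL = 0)[class])
    par1_copies <- ifelse(sex == "M",
                          c(REF = 2, EPAR = 3, DEL_HEMI = 1)[class], 2)
    xfl_copies <- ifelse(sex == "M", 1, 2) + as.numeric(aneuploid)
    yfl_copies <- ifelse(sex == "M", 1, 0)

    markers <- rbind(
      data.frame(marker_id = sprintf("inf_%02d", seq_len(spec$n_markers_informative)),
                 chrom = "chrX",
                 pos = round(seq(2776959, 2890559, length.out = spec$n_markers_informative)),
                 region = "EPAR_INTERVAL"),
      data.frame(marker_id = sprintf("par1_%02d", seq_len(spec$n_markers_par1)),
                 chrom = "chrX",
                 pos = round(seq(1500000, 2600000, length.out = spec$n_markers_par1)),
                 region = "PAR1"),
      data.frame(marker_id = sprintf("xfl_%02d", seq_len(spec$n_markers_flankX)),
                 chrom = "chrX",
                 pos = round(seq(3000000, 5000000, length.out = spec$n_markers_flankX)),
                 region = "X_FLANK"),
      data.frame(marker_id = sprintf("yfl_%02d", seq_len(spec$n_markers_flankY)),
                 chrom = "chrY",
                 pos = round(seq(3000000, 10000000, length.out = spec$n_markers_flankY)),
                 region = "Y_FLANK"))

    block <- function(copies, k) {
      spec$copy_signal * matrix(copies, n, k) + spec$background +
        matrix(rnorm(n * k, sd = spec$noise_sd), n, k)
    }
    mat <- cbind(block(inf_copies, spec$n_markers_informative),
                 block(par1_copies, spec$n_markers_par1),
                 block(xfl_copies, spec$n_markers_flankX),
                 block(yfl_copies, spec$n_markers_flankY))
    colnames(mat) <- markers$marker_id

    out <- list(
      intensities = data.frame(sample_id = sample_id, sex = sex, mat,
                               check.names = FALSE),
      markers = markers,
      truth = data.frame(sample_id = sample_id, sex = sex, class = class,
                         aneuploid = aneuploid))
    class(out) <- "epar_cohort"
    out
  })
}

#' Specify a star genealogy for Y-STR evolution
#'
#' @param n_chromosomes number of sampled chromosomes (independent lineages
#'   radiating from the founder; star topology).
#' @param G generations from founder to sample.
#' @param gen_years years per generation (default 31).
#' @param rate_table per-locus mutation probability per generation: a named
#'   numeric vector or a data frame with columns `locus` and `mu`. Defaults
#'   to the bundled 23-locus panel rates ([ppy23_panel()]).
#' @param founder founder haplotype (named integer repeat counts); by default
#'   a fixed typical haplotype is constructed over the rate-table loci.
#' @param seed integer seed.
#' @return An object of class `genealogy_spec`.
#' @export
genealogy_spec <- function(n_chromosomes, G, gen_years = 31,
                           rate_table = NULL, founder = NULL, seed = NULL) {
  if (is.null(rate_table)) {
    p <- ppy23_panel()
    rate_table <- setNames(p$mu, p$locus)
  }
  if (is.data.frame(rate_table)) {
    rate_table <- setNames(rate_table$mu, rate_table$locus)
  }
  if (any(rate_table < 0 | rate_table > 1)) stop("mutation rates must lie in [0, 1]")
  if (is.null(founder)) {
    founder <- setNames(10L + (seq_along(rate_table) %% 15L), names(rate_table))
  }
  if (!all(names(founder) == names(rate_table))) {
    stop("founder loci must match rate-table loci")
  }
  spec <- list(n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
               G = check_count(G, "G", positive = FALSE),
               gen_years = gen_years, rate_table = rate_table,
               founder = founder, seed = seed)
  class(spec) <- "genealogy_spec"
  spec
}

#' Simulate Y-STR haplotypes on a star genealogy
#'
#' Each chromosome evolves independently from the founder for `G`
#' generations under the strict single-step mutation model: per generation
#' and locus a mutation occurs with probability `mu` and shifts the repeat
#' count by +1 or -1 with equal probability. Under this model the expected
#' squared deviation from the founder is `mu * G` per locus, which is what
#' the ASD TMRCA estimator inverts.
#'
#' @param spec a [genealogy_spec()].
#' @return A list with `haplotypes` (integer matrix, samples x loci) and
#'   `founder` (named integer vector).
#' @seealso [asd_tmrca()]
#' @export
simulate_star_strs <- function(spec) {
  stopifnot(inherits(spec, "genealogy_spec"))
  with_seed(spec$seed, {
    n <- spec$n_chromosomes
    mu <- spec$rate_table
    L <- length(mu)
    counts <- matrix(rep(as.integer(spec$founder), each = n), n, L)
    if (spec$G > 0) {
      pmut <- rep(mu, each = n)
      for (g in seq_len(spec$G)) {
        step <- matrix(rbinom(n * L, 1L, pmut) * (2L * rbinom(n * L, 1L, 0.5) - 1L), n, L)
        counts <- counts + step
      }
    }
    dimnames(counts) <- list(sprintf("chr%04d", seq_len(n)), names(mu))
    list(haplotypes = counts, founder = spec$founder)
  })
}

# ---------------------------------------------------------------------------
# LTR6B recombinant junction model

next_base <- function(b, k = 1L) {
  bases <- c("A", "C", "G", "T")
  bases[((match(b, bases) - 1L + k) %% 4L) + 1L]
}

#' Construct an LTR6B two-parent junction model
#'
#' The model holds the X-specific and Y-pseudoautosomal parental elements on
#' a common 1-based coordinate frame spanning the maximal (559-bp) alignment,
#' with `-` marking positions deleted in an element that carries the short
#' allele at one of the two variable-length sites. The variant catalog lists,
#' per aligned position, the major/minor alleles of each parent, whether the
#' position is a fixed difference (disjoint allele sets), and whether it is
#' one of the two length sites.
#'
#' @param x_frame,y_frame character vectors of single bases (or `-`) of equal
#'   length: the parental elements on the alignment frame.
#' @param catalog data frame with columns `pos`, `x_major`, `x_minor`,
#'   `x_minor_freq`, `y_major`, `y_minor`, `y_minor_freq`,
#'   `fixed_difference`, `length_site`.
#' @param length_sites list with elements `distal` and `proximal`, each a
#'   list `(start, alleles)` where `alleles` is the allowed length-allele
#'   set (longest first).
#' @param length_classes observed total element lengths recognized by
#'   [map_to_references()]; by default every combination of length alleles.
#'   Stored explicitly because not all combinations are observed in nature.
#' @return An object of class `ltr6b_model`.
#' @seealso [synthetic_ltr6b_model()], [junction_sequence()]
#' @export
ltr6b_model <- function(x_frame, y_frame, catalog, length_sites,
                        length_classes = NULL) {
  if (length(x_frame) != length(y_frame)) {
    stop("parental frames must align end-to-end (equal frame length)")
  }
  if (any(catalog$pos < 1 | catalog$pos > length(x_frame))) {
    stop("catalog positions must lie within the alignment frame")
  }
  for (i in seq_len(nrow(catalog))) {
    xs <- stats::na.omit(c(catalog$x_major[i], catalog$x_minor[i]))
    ys <- stats::na.omit(c(catalog$y_major[i], catalog$y_minor[i]))
    disjoint <- length(intersect(xs, ys)) == 0L
    if (disjoint != isTRUE(catalog$fixed_difference[i])) {
      stop(sprintf("catalog position %d: fixed_difference flag inconsistent with allele sets",
                   catalog$pos[i]))
    }
  }
  if (is.null(length_classes)) {
    long_len <- vapply(length_sites, function(s) nchar(s$alleles[[1]]), integer(1))
    combos <- expand.grid(d = nchar(length_sites$distal$alleles),
                          p = nchar(length_sites$proximal$alleles))
    length_classes <- sort(unique(length(x_frame) -
                                    (long_len[["distal"]] - combos$d) -
                                    (long_len[["proximal"]] - combos$p)))
  }
  m <- list(frame_length = length(x_frame), x_frame = x_frame, y_frame = y_frame,
            catalog = catalog, length_sites = length_sites,
            length_classes = length_classes)
  class(m) <- "ltr6b_model"
  m
}

#' Built-in synthetic LTR6B model
#'
#' A deterministic synthetic two-parent model on a 559-bp frame emulating
#' the structure of the real element pair: five fixed differences within the
#' first 100 bp, 19 shared-polymorphism positions (most of them with the
#' X-element minor allele equal to the Y-element major allele, the reverse
#' being rare), and two variable-length sites -- a distal `CCACAC` site and
#' a proximal `TTACAAGGTG` site. The Y-pseudoautosomal parent carries the
#' long allele at both sites (559 bp); the X parent carries the short
#' proximal allele `TT` (551 bp). Observable junction lengths are therefore
#' 551, 554 and 559 bp. The sequences are synthetic, not the genomic
#' elements.
#'
#' @return An `ltr6b_model`.
#' @export
synthetic_ltr6b_model <- function() {
  base <- with_seed(8353, sample(c("A", "C", "G", "T"), 559, replace = TRUE))
  length_sites <- list(
    distal = list(start = 20L, alleles = c("CCACAC", "C")),
    proximal = list(start = 265L, alleles = c("TTACAAGGTG", "TT")))
  base[20:25] <- strsplit("CCACAC", "")[[1]]
  base[265:274] <- strsplit("TTACAAGGTG", "")[[1]]

  x <- y <- base
  # X element: short proximal allele (TT), 551 bp
  x[267:274] <- "-"

  fixed_pos <- c(12L, 42L, 73L, 88L, 97L)
  for (p in fixed_pos) {
    x[p] <- base[p]
    y[p] <- next_base(base[p])
  }

  shared_pos <- c(110L, 128L, 152L, 180L, 198L, 215L, 238L, 252L, 280L,
                  301L, 322L, 350L, 377L, 401L, 433L, 460L, 488L, 512L, 540L)
  cells <- c(rep("yes_no", 8), "no_yes", rep("yes_yes", 2), rep("no_no", 8))
  xmaj <- xmin <- ymaj <- ymin <- rep(NA_character_, length(shared_pos))
  xf <- yf <- rep(NA_real_, length(shared_pos))
  for (i in seq_along(shared_pos)) {
    m <- base[shared_pos[i]]; g <- next_base(m); o <- next_base(m, 2L)
    switch(cells[i],
      yes_no = { xmaj[i] <- m; xmin[i] <- g; xf[i] <- 0.2; ymaj[i] <- g },
      no_yes = { xmaj[i] <- m; ymaj[i] <- g; ymin[i] <- m; yf[i] <- 0.1 },
      yes_yes = { xmaj[i] <- m; xmin[i] <- g; xf[i] <- 0.15; ymaj[i] <- g; ymin[i] <- m; yf[i] <- 0.1 },
      no_no = { xmaj[i] <- m; xmin[i] <- o; xf[i] <- 0.1; ymaj[i] <- m })
    x[shared_pos[i]] <- xmaj[i]
    y[shared_pos[i]] <- ymaj[i]
  }

  catalog <- rbind(
    data.frame(pos = fixed_pos,
               x_major = x[fixed_pos], x_minor = NA_character_, x_minor_freq = NA_real_,
               y_major = y[fixed_pos], y_minor = NA_character_, y_minor_freq = NA_real_,
               fixed_difference = TRUE, length_site = NA_character_),
    data.frame(pos = shared_pos,
               x_major = xmaj, x_minor = xmin, x_minor_freq = xf,
               y_major = ymaj, y_minor = ymin, y_minor_freq = yf,
               fixed_difference = FALSE, length_site = NA_character_),
    data.frame(pos = c(20L, 265L),
               x_major = c("CCACAC", "TT"), x_minor = NA_character_, x_minor_freq = NA_real_,
               y_major = c("CCACAC", "TTACAAGGTG"), y_minor = NA_character_, y_minor_freq = NA_real_,
               fixed_difference = c(FALSE, TRUE),
               length_site = c("distal", "proximal")))
  catalog <- catalog[order(catalog$pos), ]
  rownames(catalog) <- NULL
  ltr6b_model(x, y, catalog, length_sites, length_classes = c(551L, 554L, 559L))
}

#' Build one recombinant junction sequence
#'
#' For an ePAR junction with crossover coordinate `c`, positions strictly
#' below `c` take the X-element state and positions at or above `c` take the
#' Y-element state; a reciprocal-deletion junction swaps the parent roles at
#' the same coordinate. Coordinates are 1-based on the alignment frame from
#' the distal (5') end.
#'
#' @param model an [ltr6b_model()].
#' @param crossover integer crossover coordinate in `1..frame_length`.
#' @param role `"EPAR"` or `"DELETION"`.
#' @param x_frame,y_frame optional parental frame overrides (e.g. to place a
#'   variant length allele on a parent).
#' @return A single junction sequence (character scalar, gaps removed).
#' @export
junction_sequence <- function(model, crossover, role = c("EPAR", "DELETION"),
                              x_frame = NULL, y_frame = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(model, "ltr6b_model"))
  if (!is.numeric(crossover) || length(crossover) != 1L ||
      crossover < 1 || crossover > model$frame_length) {
    stop(sprintf("crossover coordinate must lie within the element (1..%d), got %s",
                 model$frame_length, format(crossover)))
  }
  for (site in model$length_sites) {
    e <- site$start + nchar(site$alleles[[1]]) - 1L
    if (crossover > site$start && crossover <= e) {
      stop("crossover coordinate falls inside a variable-length site; the hybrid length allele would be undefined")
    }
  }
  xf <- if (is.null(x_frame)) model$x_frame else x_frame
  yf <- if (is.null(y_frame)) model$y_frame else y_frame
  idx <- seq_len(model$frame_length)
  frame <- if (role == "EPAR") ifelse(idx < crossover, xf, yf)
           else ifelse(idx < crossover, yf, xf)
  paste(frame[frame != "-"], collapse = "")
}

#' Specify planted NAHR origin events on a haplogroup tree
#'
#' @param tree a [haplogroup_tree()] or an `ape` `phylo` object with unique
#'   tip and node labels.
#' @param events data frame with columns `branch` (a tip or internal node
#'   label; the event applies to all tips of that clade), `crossover`
#'   (element coordinate) and `type_id`.
#' @param sampled_tips named integer vector: number of sampled carriers per
#'   tip. Tips without an ancestral event yield no junction samples.
#' @param seed integer seed (reserved for stochastic extensions; the
#'   generator itself is deterministic).
#' @return An object of class `origin_scenario`.
#' @export
origin_scenario <- function(tree, events, sampled_tips, seed = NULL) {
  tree <- as_haplogroup_tree(tree)
  labs <- c(tree$phylo$tip.label, tree$phylo$node.label)
  bad <- setdiff(events$branch, labs)
  if (length(bad)) stop("unknown event branches: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(sampled_tips), tree$phylo$tip.label)
  if (length(bad)) stop("unknown sampled tips: ", paste(bad, collapse = ", "))
  s <- list(tree = tree, events = events, sampled_tips = sampled_tips, seed = seed)
  class(s) <- "origin_scenario"
  s
}

#' Simulate a set of recombinant junction sequences from planted origins
#'
#' Each planted event generates a junction sequence at its crossover
#' coordinate; the junction type propagates down the tree to the sampled
#' tips of the event clade (the deepest applicable event wins when events
#' are nested). Returns the sequences together with the planted truth.
#'
#' @param model an [ltr6b_model()].
#' @param scenario an [origin_scenario()].
#' @param role `"EPAR"` or `"DELETION"` junction orientation.
#' @return A list with `sequences` (named character vector), `crossovers`
#'   (data frame `sample_id`, `crossover`), and `origins` (data frame
#'   `sample_id`, `tip`, `type_id` -- the origin table consumed by
#'   [min_origins()]).
#' @export
simulate_junction_set <- function(model, scenario, role = c("EPAR", "DELETION")) {
  role <- match.arg(role)
  stopifnot(inherits(model, "ltr6b_model"), inherits(scenario, "origin_scenario"))
  phy <- scenario$tree$phylo
  ev <- scenario$events
  if (any(ev$crossover < 1 | ev$crossover > model$frame_length)) {
    stop(sprintf("crossover coordinates must lie within the element (1..%d)",
                 model$frame_length))
  }
  labs <- c(phy$tip.label, phy$node.label)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L

  # tips covered by each event clade, event depth = path length from root
  clade_tips <- function(label) {
    node <- match(label, labs)
    if (node <= ntip) return(phy$tip.label[node])
    ape::extract.clade(phy, node)$tip.label
  }
  depth <- vapply(ev$branch, function(b) {
    length(ape::nodepath(phy, root, match(b, labs)))
  }, integer(1))

  seqs <- crossovers <- origins <- list()
  for (tip in names(scenario$sampled_tips)) {
    covering <- which(vapply(ev$branch, function(b) tip %in% clade_tips(b), logical(1)))
    if (!length(covering)) next
    e <- covering[order(depth[covering], covering)][length(covering)]
    k <- scenario$sampled_tips[[tip]]
    if (k < 1) next
    ids <- sprintf("%s_%02d", tip, seq_len(k))
    seq1 <- junction_sequence(model, ev$crossover[e], role = role)
    seqs[[tip]] <- setNames(rep(seq1, k), ids)
    crossovers[[tip]] <- data.frame(sample_id = ids, crossover = ev$crossover[e])
    origins[[tip]] <- data.frame(sample_id = ids, tip = tip, type_id = ev$type_id[e])
  }
  list(sequences = unlist(unname(seqs)),
       crossovers = do.call(rbind, c(crossovers, list(make.row.names = FALSE))),
       origins = do.call(rbind, c(origins, list(make.row.names = FALSE))),
       role = role)
}

#' Specify a synthetic phenotype table
#'
#' @param n_quantitative,n_binary numbers of quantitative (`Q1..`) and
#'   binary (`B1..`) traits.
#' @param effect_map named numeric vector of planted carrier effects:
#'   mean shifts in SD units for quantitative traits, log-odds shifts for
#'   binary traits; unnamed traits are null.
#' @param baseline_prevalence baseline prevalence of each binary trait
#'   (scalar or per-trait vector), strictly inside (0, 1).
#' @param seed integer seed.
#' @return An object of class `pheno_spec`.
#' @export
pheno_spec <- function(n_quantitative = 10, n_binary = 10,
                       effect_map = numeric(0), baseline_prevalence = 0.01,
                       seed = NULL) {
  nq <- check_count(n_quantitative, "n_quantitative", positive = FALSE)
  nb <- check_count(n_binary, "n_binary", positive = FALSE)
  traits <- c(sprintf("Q%d", seq_len(nq)), sprintf("B%d", seq_len(nb)))
  if (length(effect_map) && !all(names(effect_map) %in% traits)) {
    stop("effect_map names must be a subset of the generated traits")
  }
  prev <- rep_len(baseline_prevalence, nb)
  if (nb > 0 && any(prev <= 0 | prev >= 1)) stop("prevalences must lie strictly in (0, 1)")
  spec <- list(n_quantitative = nq, n_binary = nb, effect_map = effect_map,
               baseline_prevalence = prev, seed = seed)
  class(spec) <- "pheno_spec"
  spec
}

#' Simulate phenotypes with planted carrier effects
#'
#' Quantitative traits are standard Gaussian with a planted mean shift for
#' carriers; binary traits are Bernoulli with a planted log-odds shift on
#' the baseline prevalence. Traits absent from the effect map are null.
#'
#' @param carrier logical vector of carrier status (optionally named by
#'   sample id).
#' @param spec a [pheno_spec()].
#' @return A data frame with `sample_id` and one column per trait.
#' @export
simulate_phenotypes <- function(carrier, spec) {
  stopifnot(inherits(spec, "pheno_spec"), is.logical(carrier), !anyNA(carrier))
  with_seed(spec$seed, {
    n <- length(carrier)
    ids <- if (!is.null(names(carrier))) names(carrier) else sprintf("S%06d", seq_len(n))
    out <- data.frame(sample_id = ids)
    for (j in seq_len(spec$n_quantitative)) {
      nm <- sprintf("Q%d", j)
      shift <- if (nm %in% names(spec$effect_map)) spec$effect_map[[nm]] else 0
      out[[nm]] <- rnorm(n) + shift * carrier
    }
    for (j in seq_len(spec$n_binary)) {
      nm <- sprintf("B%d", j)
      shift <- if (nm %in% names(spec$effect_map)) spec$effect_map[[nm]] else 0
      p <- plogis(qlogis(spec$baseline_prevalence[j]) + shift * carrier)
      out[[nm]] <- rbinom(n, 1L, p)
    }
    out
  })
}
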