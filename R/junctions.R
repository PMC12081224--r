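# Recombinant LTR6B junction analysis: mapping sequences onto the
# two-parent variant catalog, exact-sequence typing, crossover-interval
# inference, distinct-chromosome counting and the allele-sharing test.

site_positions <- function(site) {
  seq(site$start, site$start + nchar(site$alleles[[1]]) - 1L)
}

#' Map a junction sequence onto the two-parent catalog frame
#'
#' Aligns an observed recombinant element to the model's coordinate frame.
#' Gaps are confined to the two variable-length sites, so the alignment is
#' deterministic: the observed total length identifies the length-allele
#' combination, and gap columns are inserted at the short site(s). Each
#' catalog position is then called `X` (matches an X-element-only allele),
#' `Y` (Y-element-only), `shared` (present in both parents) or `missing`.
#'
#' @param sequence junction sequence (character scalar).
#' @param model an [ltr6b_model()].
#' @param sample_id identifier stored on the observation.
#' @param role junction role: `"EPAR"` (X-derived segment distal, Y-derived
#'   proximal) or `"DELETION"` (the reverse).
#' @param flank_haplotype optional named character vector of flanking-SNP
#'   states (deletion junctions), stored verbatim.
#' @return An object of class `junction_observation`: `sample_id`, `states`
#'   (named by catalog position), `frame`, `length_class`, `role`,
#'   `flank_haplotype`, `sequence`.
#' @export
map_to_references <- function(sequence, model, sample_id = NA_character_,
                              role = c("EPAR", "DELETION"),
                              flank_haplotype = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(model, "ltr6b_model"), is.character(sequence), length(sequence) == 1L)
  sites <- model$length_sites
  long_len <- vapply(sites, function(s) nchar(s$alleles[[1]]), integer(1))

  combos <- expand.grid(distal = sites$distal$alleles,
                        proximal = sites$proximal$alleles,
                        stringsAsFactors = FALSE)
  combos$length <- model$frame_length -
    (long_len["distal"] - nchar(combos$distal)) -
    (long_len["proximal"] - nchar(combos$proximal))
  combos <- combos[combos$length %in% model$length_classes, ]

  obs_len <- nchar(sequence)
  hit <- which(combos$length == obs_len)
  if (!length(hit)) {
    stop(sprintf("junction length %d bp is outside the recognized classes {%s}",
                 obs_len, paste(sort(unique(combos$length)), collapse = ", ")))
  }
  combo <- combos[hit[1], ]

  gap <- logical(model$frame_length)
  for (nm in c("distal", "proximal")) {
    pos <- site_positions(sites[[nm]])
    keep <- nchar(combo[[nm]])
    gap[pos[seq_along(pos) > keep]] <- TRUE
  }
  frame <- rep("-", model$frame_length)
  frame[!gap] <- strsplit(sequence, "")[[1]]

  cat_ <- model$catalog
  states <- character(nrow(cat_))
  for (i in seq_len(nrow(cat_))) {
    if (!is.na(cat_$length_site[i])) {
      pos <- site_positions(sites[[cat_$length_site[i]]])
      obs <- paste(frame[pos][frame[pos] != "-"], collapse = "")
    } else {
      obs <- frame[cat_$pos[i]]
    }
    xs <- stats::na.omit(c(cat_$x_major[i], cat_$x_minor[i]))
    ys <- stats::na.omit(c(cat_$y_major[i], cat_$y_minor[i]))
    states[i] <- if (obs == "-" || (!obs %in% xs && !obs %in% ys)) "missing"
      else if (obs %in% xs && obs %in% ys) "shared"
      else if (obs %in% xs) "X" else "Y"
  }
  names(states) <- cat_$pos
  out <- list(sample_id = sample_id, states = states, frame = frame,
              length_class = obs_len, role = role,
              flank_haplotype = flank_haplotype, sequence = sequence)
  class(out) <- "junction_observation"
  out
}

as_sequence_vector <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "junction_observation")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "junction_observation"))) {
    return(setNames(vapply(x, `[[`, character(1), "sequence"),
                    vapply(x, `[[`, character(1), "sample_id")))
  }
  stop("expected a named character vector of sequences or junction observations")
}

#' Group junction sequences into exact-sequence types
#'
#' A junction type is an exact sequence identity class (no mismatch
#' tolerance). Published reference types are matched first by canonical
#' sequence and keep their names; newly observed sequences are numbered in
#' first-seen order starting after the highest published index (or, with
#' `canonical_order = "sorted"`, in lexicographic sequence order so that
#' ids are stable under input reordering).
#'
#' @param x named character vector of sequences, or a list of
#'   [map_to_references()] observations.
#' @param published optional named character vector of reference canonical
#'   sequences (e.g. `c(Junc1 = ..., Junc2 = ...)`).
#' @param prefix name prefix for new types (default `"Junc"`).
#' @param canonical_order `"first_seen"` (default) or `"sorted"`.
#' @return An object of class `junction_registry`: `types` (data frame
#'   `type_id`, `sequence`, `n_members`) and `assignment` (named character,
#'   sample -> type).
#' @export
classify_junction_types <- function(x, published = NULL, prefix = "Junc",
                                    canonical_order = c("first_seen", "sorted")) {
  canonical_order <- match.arg(canonical_order)
  seqs <- as_sequence_vector(x)
  if (!length(seqs)) stop("no observations to classify")
  if (!is.null(published) && anyDuplicated(published)) {
    stop("published canonical sequences must be pairwise distinct")
  }

  type_of <- if (is.null(published)) character(0)
             else setNames(names(published), published)  # sequence -> id
  nxt <- 1L
  if (!is.null(published)) {
    idx <- suppressWarnings(as.integer(sub(paste0("^", prefix), "", names(published))))
    if (any(!is.na(idx))) nxt <- max(idx, na.rm = TRUE) + 1L
  }
  new_seqs <- unique(seqs[!seqs %in% names(type_of)])
  if (canonical_order == "sorted") new_seqs <- sort(new_seqs)
  for (s in new_seqs) {
    type_of[[s]] <- sprintf("%s%d", prefix, nxt)
    nxt <- nxt + 1L
  }
  assignment <- setNames(unname(type_of[seqs]), names(seqs))
  used <- type_of[names(type_of) %in% seqs]
  types <- data.frame(type_id = unname(used), sequence = names(used),
                      n_members = as.integer(table(assignment)[unname(used)]),
                      row.names = NULL)
  out <- list(types = types, assignment = assignment)
  class(out) <- "junction_registry"
  out
}

#' @export
print.junction_registry <- function(x, ...) {
  cat(sprintf("Junction registry: %d type(s), %d observation(s)\n",
              nrow(x$types), length(x$assignment)))
  for (i in seq_len(nrow(x$types))) {
    cat(sprintf("  %s: %d member(s), %d bp\n", x$types$type_id[i],
                x$types$n_members[i], nchar(x$types$sequence[i])))
  }
  invisible(x)
}

#' Infer the crossover interval of a recombinant junction
#'
#' Informative positions are the fixed differences between the parental
#' elements (`FIXED_ONLY`) or all positions where the parental major
#' alleles differ (`MAJOR_ALLELE`). For an ePAR-role junction the crossover
#' lies in the open interval between the last informative position in the X
#' state and the first informative position in the Y state; a deletion-role
#' junction swaps the parents. If one side has no informative support the
#' corresponding bound is open (`NA`) and the interval is indeterminate.
#' Interleaved parental states (an X state proximal to a Y state for an
#' ePAR junction) indicate a complex exchange such as gene conversion and
#' raise an error rather than being truncated silently.
#'
#' @param observation a [map_to_references()] observation.
#' @param model the [ltr6b_model()] whose catalog defines informative
#'   positions.
#' @param mode `"FIXED_ONLY"` (default) or `"MAJOR_ALLELE"`.
#' @return An object of class `crossover_interval`: `lo`, `hi` (element
#'   coordinates or `NA`), `status` (`"determinate"`/`"indeterminate"`),
#'   `mode`, `role`.
#' @export
infer_crossover_interval <- function(observation, model,
                                     mode = c("FIXED_ONLY", "MAJOR_ALLELE")) {
  mode <- match.arg(mode)
  stopifnot(inherits(observation, "junction_observation"),
            inherits(model, "ltr6b_model"))
  cat_ <- model$catalog
  if (mode == "FIXED_ONLY") {
    rows <- which(cat_$fixed_difference)
    calls <- observation$states[as.character(cat_$pos[rows])]
  } else {
    rows <- which(cat_$x_major != cat_$y_major)
    calls <- vapply(rows, function(i) {
      if (!is.na(cat_$length_site[i])) {
        pos <- site_positions(model$length_sites[[cat_$length_site[i]]])
        obs <- paste(observation$frame[pos][observation$frame[pos] != "-"], collapse = "")
      } else {
        obs <- observation$frame[cat_$pos[i]]
      }
      if (obs == cat_$x_major[i]) "X" else if (obs == cat_$y_major[i]) "Y" else "missing"
    }, character(1))
  }
  pos <- cat_$pos[rows]
  posX <- pos[calls == "X"]
  posY <- pos[calls == "Y"]
  if (observation$role == "EPAR") {
    distal <- posX; proximal <- posY
  } else {
    distal <- posY; proximal <- posX
  }
  if (length(distal) && length(proximal) && max(distal) > min(proximal)) {
    stop(sprintf(paste0("inconsistent parental states (interleaved at positions %d and %d): ",
                        "possible gene conversion or complex exchange"),
                 min(proximal), max(distal)))
  }
  lo <- if (length(distal)) max(distal) else NA_integer_
  hi <- if (length(proximal)) min(proximal) else NA_integer_
  out <- list(lo = lo, hi = hi,
              status = if (is.na(lo) || is.na(hi)) "indeterminate" else "determinate",
              mode = mode, role = observation$role)
  class(out) <- "crossover_interval"
  out
}

#' @export
print.crossover_interval <- function(x, ...) {
  cat(sprintf("Crossover interval (%s, %s role): (%s, %s) -- %s\n", x$mode, x$role,
              ifelse(is.na(x$lo), "open", x$lo), ifelse(is.na(x$hi), "open", x$hi),
              x$status))
  invisible(x)
}

#' Count distinct rearranged chromosomes
#'
#' Two observations represent the same rearranged chromosome when they share
#' both the junction type and the flanking-SNP haplotype; the partition key
#' is the pair `(type_id, flank_haplotype)`.
#'
#' @param observations data frame with columns `sample_id`, `type_id` and
#'   optionally `flank_haplotype` (missing/`NA` flanks collapse to one
#'   level).
#' @return A list: `n_distinct`, `partition` (data frame `type_id`,
#'   `flank_haplotype`, `n_members`), `key` (named character per sample).
#' @export
distinct_rearranged_chromosomes <- function(observations) {
  stopifnot(is.data.frame(observations), nrow(observations) > 0,
            "type_id" %in% names(observations))
  flank <- if ("flank_haplotype" %in% names(observations)) {
    ifelse(is.na(observations$flank_haplotype), "", observations$flank_haplotype)
  } else rep("", nrow(observations))
  key <- paste(observations$type_id, flank, sep = "|")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  partition <- data.frame(type_id = parts[, 1],
                          flank_haplotype = if (ncol(parts) > 1) parts[, 2] else "",
                          n_members = as.integer(tab), row.names = NULL)
  list(n_distinct = length(tab), partition = partition,
       key = setNames(key, observations$sample_id))
}

#' One-tailed exact test of allele-sharing asymmetry between the parents
#'
#' Classifies every shared-polymorphism position of the catalog by two
#' binary properties: whether the X-element minor allele equals the
#' Y-element major allele, and whether the Y-element minor allele equals
#' the X-element major allele. The resulting 2x2 table is tested with a
#' one-tailed Fisher exact test (upper hypergeometric tail on the first
#' cell), asking whether the first relation is over-represented. Degenerate
#' margins give `p = 1` by convention.
#'
#' @param model an [ltr6b_model()] or its catalog data frame.
#' @return A list of class `allele_sharing_test`: `p.value`, `table`
#'   (2x2), `n_positions`.
#' @export
allele_sharing_test <- function(model) {
  cat_ <- if (inherits(model, "ltr6b_model")) model$catalog else model
  shared <- !cat_$fixed_difference & (!is.na(cat_$x_minor) | !is.na(cat_$y_minor))
  if (!any(shared)) stop("catalog has no shared-polymorphism positions")
  sub <- cat_[shared, ]
  A <- !is.na(sub$x_minor) & sub$x_minor == sub$y_major
  B <- !is.na(sub$y_minor) & sub$y_minor == sub$x_major
  tab <- matrix(c(sum(A & B), sum(A & !B), sum(!A & B), sum(!A & !B)),
                2, 2, byrow = TRUE,
                dimnames = list(x_minor_is_y_major = c("yes", "no"),
                                y_minor_is_x_major = c("yes", "no")))
  p <- fisher_onetail_p(tab)
  out <- list(p.value = p, table = tab, n_positions = nrow(sub))
  class(out) <- "allele_sharing_test"
  out
}

# Upper-tail exact hypergeometric p for cell [1,1] of a 2x2 table with
# fixed margins: P(A >= a_obs).
fisher_onetail_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  hi <- min(r1, c1)
  sum(dhyper(a:hi, c1, N - c1, r1))
}

#' @export
print.allele_sharing_test <- function(x, ...) {
  cat(sprintf("Allele-sharing asymmetry over %d shared-polymorphism positions\n",
              x$n_positions))
  print(x$table)
  cat(sprintf("one-tailed exact p = %.4g\n", x$p.value))
  invisible(x)
}

#' Write / read junction sequences as FASTA
#'
#' @param sequences named character vector of junction sequences.
#' @param path FASTA file path.
#' @return `write_junction_fasta` returns `path` invisibly;
#'   `read_junction_fasta` returns a named character vector.
#' @export
write_junction_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_junction_fasta
#' @export
read_junction_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
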