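test_that("parental sequences map without foreign states", {
  m <- synthetic_ltr6b_model()
  y_obs <- map_to_references(paste(m$y_frame[m$y_frame != "-"], collapse = ""), m)
  expect_false(any(y_obs$states == "X"))
  expect_equal(y_obs$length_class, 559)
  x_obs <- map_to_references(paste(m$x_frame[m$x_frame != "-"], collapse = ""), m)
  expect_false(any(x_obs$states == "Y"))
  expect_equal(x_obs$length_class, 551)
  expect_error(map_to_references(strrep("A", 500), m), "outside the recognized")
})

test_that("hybrid sequences carry X states distal and Y states proximal to the crossover", {
  m <- synthetic_ltr6b_model()
  fixed <- m$catalog$pos[m$catalog$fixed_difference & is.na(m$catalog$length_site)]
  c_ <- 80L  # between fixed positions 73 and 88
  obs <- map_to_references(junction_sequence(m, c_), m)
  st <- obs$states[as.character(fixed)]
  expect_true(all(st[fixed < c_] == "X"))
  expect_true(all(st[fixed >= c_] == "Y"))
})

test_that("junction typing deduplicates exact sequences and honours published types", {
  m <- synthetic_ltr6b_model()
  s1 <- junction_sequence(m, 50)
  s2 <- junction_sequence(m, 80)
  s3 <- junction_sequence(m, 300)
  seqs <- setNames(c(s1, s1, s2, s3, s3), paste0("v", 1:5))
  reg <- classify_junction_types(seqs)
  expect_equal(nrow(reg$types), 3)
  expect_equal(sum(reg$types$n_members), 5)
  expect_identical(reg$assignment[["v1"]], reg$assignment[["v2"]])

  # published canonical sequences keep their names; new ids continue after them
  reg2 <- classify_junction_types(seqs, published = c(Junc1 = s2, Junc2 = "AAA"))
  expect_equal(unname(reg2$assignment[["v3"]]), "Junc1")
  expect_setequal(reg2$types$type_id, c("Junc1", "Junc3", "Junc4"))

  # type partition is invariant under input order
  set.seed(2)
  for (i in 1:5) {
    perm <- sample(seq_along(seqs))
    rp <- classify_junction_types(seqs[perm], canonical_order = "sorted")
    rs <- classify_junction_types(seqs, canonical_order = "sorted")
    expect_identical(rp$assignment[names(seqs)], rs$assignment)
  }
  expect_error(classify_junction_types(character(0)), "no observations")
  expect_error(classify_junction_types(seqs, published = c(J1 = "AA", J2 = "AA")),
               "distinct")
})

test_that("crossover intervals follow the informative-position rule", {
  m <- synthetic_ltr6b_model()
  # fixed informative positions: 12, 42, 73, 88, 97 (+ proximal length site 265)
  obs <- map_to_references(junction_sequence(m, 50), m)
  ci <- infer_crossover_interval(obs, m)
  expect_equal(ci$lo, 42)
  expect_equal(ci$hi, 73)
  expect_equal(ci$status, "determinate")

  # all informative sites in the Y state -> distal bound open, indeterminate
  obs_y <- map_to_references(junction_sequence(m, 1), m)
  ci_y <- infer_crossover_interval(obs_y, m)
  expect_true(is.na(ci_y$lo))
  expect_equal(ci_y$status, "indeterminate")

  # interleaved parental states flag a possible gene conversion
  bad <- obs
  bad$states[["12"]] <- "Y"
  bad$states[["42"]] <- "X"
  expect_error(infer_crossover_interval(bad, m), "gene conversion")
})

test_that("round trip: inferred intervals contain the simulated crossover", {
  m <- synthetic_ltr6b_model()
  fixed <- sort(m$catalog$pos[m$catalog$fixed_difference])
  bad_pos <- unlist(lapply(m$length_sites, function(s) {
    seq(s$start + 1L, s$start + nchar(s$alleles[[1]]) - 1L)
  }))
  set.seed(77)
  for (i in 1:200) {
    g <- sample(length(fixed) - 1L, 1)
    lo <- fixed[g]; hi <- fixed[g + 1L]
    cand <- setdiff(seq(lo + 1L, hi - 1L), bad_pos)
    c_ <- sample(cand, 1)
    role <- sample(c("EPAR", "DELETION"), 1)
    obs <- map_to_references(junction_sequence(m, c_, role), m, role = role)
    ci <- infer_crossover_interval(obs, m)
    expect_equal(ci$lo, lo)
    expect_equal(ci$hi, hi)
    expect_true(ci$lo < c_ && c_ < ci$hi)
  }
})

test_that("reciprocal products at one crossover share the fixed-only interval", {
  m <- synthetic_ltr6b_model()
  for (c_ in c(30, 80, 95, 150)) {
    ep <- infer_crossover_interval(
      map_to_references(junction_sequence(m, c_, "EPAR"), m, role = "EPAR"), m)
    dl <- infer_crossover_interval(
      map_to_references(junction_sequence(m, c_, "DELETION"), m, role = "DELETION"), m)
    expect_equal(ep$lo, dl$lo)
    expect_equal(ep$hi, dl$hi)
  }
})

test_that("major-allele intervals are never wider than fixed-only intervals", {
  m <- synthetic_ltr6b_model()
  valid <- distinct_crossover_points(m, 10)
  for (c_ in valid[valid > 1]) {
    obs <- map_to_references(junction_sequence(m, c_), m)
    fo <- infer_crossover_interval(obs, m, "FIXED_ONLY")
    ma <- infer_crossover_interval(obs, m, "MAJOR_ALLELE")
    if (fo$status == "determinate" && ma$status == "determinate") {
      expect_gte(ma$lo, fo$lo)
      expect_lte(ma$hi, fo$hi)
    }
  }
})

test_that("distinct rearranged chromosomes partition by type and flanking haplotype", {
  obs <- data.frame(
    sample_id = sprintf("d%d", 1:8),
    type_id = c("Del_1", "Del_1", "Del_2", "Del_2", "Del_2", "Del_3", "Del_3", "Del_3"),
    flank_haplotype = c("AA|G", "AA|G", "AA|G", "AT|G", "AT|G", NA, NA, NA))
  part <- distinct_rearranged_chromosomes(obs)
  expect_equal(part$n_distinct, 4)  # Del_2 split by two flanking haplotypes
  expect_equal(sum(part$partition$n_members), 8)
  # all identical -> 1
  one <- distinct_rearranged_chromosomes(data.frame(sample_id = "a", type_id = "t"))
  expect_equal(one$n_distinct, 1)
})

test_that("the one-tailed exact test matches enumeration and fisher.test", {
  # worked example: [[5,0],[1,4]] -> 6 / C(10,5)
  tab <- matrix(c(5, 0, 1, 4), 2, 2, byrow = TRUE)
  expect_equal(eparscan:::fisher_onetail_p(tab), 6 / choose(10, 5))
  # degenerate margin -> 1 by convention
  expect_equal(eparscan:::fisher_onetail_p(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), 1)
  set.seed(11)
  for (i in 1:200) {
    t2 <- matrix(rpois(4, sample(1:6, 1)), 2, 2)
    p <- eparscan:::fisher_onetail_p(t2)
    expect_equal(p, brute_fisher_onetail(t2), tolerance = 1e-12)
    if (all(rowSums(t2) > 0) && all(colSums(t2) > 0)) {
      expect_equal(p, fisher.test(t2, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  }
  # catalog-level wrapper agrees with the oracle on its own table
  m <- synthetic_ltr6b_model()
  ast <- allele_sharing_test(m)
  expect_equal(ast$n_positions, 19)
  expect_equal(ast$p.value, brute_fisher_onetail(ast$table))
})

test_that("junction FASTA round-trips through Biostrings", {
  m <- synthetic_ltr6b_model()
  seqs <- setNames(c(junction_sequence(m, 50), junction_sequence(m, 300)),
                   c("a", "b"))
  path <- tempfile(fileext = ".fasta")
  write_junction_fasta(seqs, path)
  expect_identical(read_junction_fasta(path), seqs)
})
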