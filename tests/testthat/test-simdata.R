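test_that("zero-noise cohorts put carrier males exactly at the female two-copy level", {
  co <- simulate_cohort(cohort_spec(n_males = 200, n_females = 200,
                                    freq_epar = 0.1, noise_sd = 0,
                                    aneuploidy_fraction = 0, seed = 1))
  inf <- co$markers$marker_id[co$markers$region == "EPAR_INTERVAL"]
  males <- co$intensities$sex == "M"
  carriers <- co$truth$class == "EPAR" & males
  f_ref <- co$truth$class == "REF" & !males
  expect_true(any(carriers))
  for (mk in inf[1:5]) {
    expect_equal(unique(co$intensities[[mk]][carriers]),
                 unique(co$intensities[[mk]][f_ref]))
  }
})

test_that("cohort simulation is reproducible under a fixed seed and validates its spec", {
  s <- cohort_spec(n_males = 100, n_females = 100, seed = 42)
  a <- simulate_cohort(s)
  b <- simulate_cohort(s)
  expect_identical(a, b)
  expect_error(cohort_spec(n_males = 100, n_females = 100, freq_epar = 1.2),
               "proportion")
  expect_error(cohort_spec(n_males = 0, n_females = 10), "positive")
  expect_error(cohort_spec(n_males = 10, n_females = 10, noise_sd = -1), "noise_sd")
  expect_error(simulate_cohort(cohort_spec(n_males = 10, n_females = 0)),
               "female")
})

test_that("planted carrier frequency is recovered within the binomial interval", {
  n <- 20000
  fe <- 0.0077
  co <- simulate_cohort(cohort_spec(n_males = n, n_females = 2000, freq_epar = fe,
                                    seed = 99))
  k <- sum(co$truth$class == "EPAR" & co$truth$sex == "M")
  expect_gte(k, qbinom(0.025, n, fe))
  expect_lte(k, qbinom(0.975, n, fe))
})

test_that("STR star evolution matches the single-step ASD expectation", {
  # all-zero rates: every haplotype equals the founder
  g0 <- genealogy_spec(50, 80, rate_table = c(L1 = 0, L2 = 0), seed = 5)
  s0 <- simulate_star_strs(g0)
  expect_true(all(sweep(s0$haplotypes, 2, s0$founder) == 0))

  # E[(a - founder)^2] = mu * G per locus
  mu <- 0.002; G <- 65; n <- 10000
  g <- genealogy_spec(n, G, rate_table = c(L1 = mu), founder = c(L1 = 15), seed = 3)
  s <- simulate_star_strs(g)
  asd <- mean((s$haplotypes[, 1] - 15)^2)
  se <- sd((s$haplotypes[, 1] - 15)^2) / sqrt(n)
  expect_lt(abs(asd - mu * G), 3 * se)

  # determinism
  expect_identical(simulate_star_strs(g)$haplotypes, s$haplotypes)
})

test_that("junction generation respects the crossover semantics", {
  m <- synthetic_ltr6b_model()
  # boundary: c = 1 reproduces the Y-PAR parental element
  expect_identical(junction_sequence(m, 1, "EPAR"),
                   paste(m$y_frame[m$y_frame != "-"], collapse = ""))
  expect_identical(junction_sequence(m, 1, "DELETION"),
                   paste(m$x_frame[m$x_frame != "-"], collapse = ""))
  expect_error(junction_sequence(m, 0), "within the element")
  expect_error(junction_sequence(m, 560), "within the element")
  expect_error(junction_sequence(m, 267), "length site")
})

test_that("reciprocal junction pairs are complementary at every polymorphic position", {
  m <- synthetic_ltr6b_model()
  for (c_ in c(30, 80, 150, 300, 450)) {
    ep <- map_to_references(junction_sequence(m, c_, "EPAR"), m, role = "EPAR")
    dl <- map_to_references(junction_sequence(m, c_, "DELETION"), m, role = "DELETION")
    # at fixed differences (disjoint parental allele sets) exactly one of the
    # pair carries the X state and the other the Y state
    fixed <- m$catalog$pos[m$catalog$fixed_difference]
    for (p in as.character(fixed)) {
      states <- sort(c(ep$states[[p]], dl$states[[p]]))
      expect_identical(states, c("X", "Y"))
    }
    # at overlapping-allele polymorphisms the pair is never contradictory:
    # the two products never both claim the same parent
    poly <- m$catalog$pos[m$catalog$x_major != m$catalog$y_major &
                            !m$catalog$fixed_difference]
    for (p in as.character(poly)) {
      states <- c(ep$states[[p]], dl$states[[p]])
      expect_false(all(states == "X") || all(states == "Y"))
    }
    # non-polymorphic positions cannot distinguish the pair
    same <- m$catalog$pos[m$catalog$x_major == m$catalog$y_major &
                            is.na(m$catalog$x_minor) & is.na(m$catalog$y_minor)]
    for (p in as.character(same)) {
      expect_identical(ep$states[[p]], dl$states[[p]])
    }
  }
})

test_that("planted origin events propagate to sampled tips and bound min_origins", {
  m <- synthetic_ltr6b_model()
  tree <- reference_tree()
  tips <- tree$phylo$tip.label
  cpoints <- distinct_crossover_points(m, 6)
  # candidate branches with pairwise-disjoint clades: planted events must not
  # nest, otherwise a later event overwrites part of an earlier clade and the
  # earlier type's presence is no longer a union of whole clades
  labs <- c(tips, "I2a", "R1b", "I1")
  clades <- lapply(labs, function(b) {
    node <- match(b, c(tips, tree$phylo$node.label))
    if (node <= length(tips)) tips[node] else ape::extract.clade(tree$phylo, node)$tip.label
  })
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    pick <- integer(0)
    for (j in sample(seq_along(labs))) {
      if (!any(vapply(pick, function(p) length(intersect(clades[[j]], clades[[p]])) > 0,
                      logical(1)))) pick <- c(pick, j)
      if (length(pick) == k) break
    }
    events <- data.frame(branch = labs[pick],
                         crossover = sample(cpoints, length(pick), replace = TRUE),
                         type_id = sprintf("t%d", seq_along(pick)))
    k <- length(pick)
    sc <- origin_scenario(tree, events,
                          sampled_tips = setNames(rep(2L, length(tips)), tips))
    sim <- simulate_junction_set(m, sc)
    expect_lte(min_origins(sim$origins, tree)$n_origins, k)
  }
  expect_error(origin_scenario(tree, data.frame(branch = "nope", crossover = 1,
                                                type_id = "t"), c(`K-M9` = 1L)),
               "unknown event branches")
})

test_that("phenotype generator plants effects and is null otherwise", {
  carrier <- rep(c(TRUE, FALSE), c(2000, 18000))
  sp <- pheno_spec(n_quantitative = 2, n_binary = 1,
                   effect_map = c(Q1 = 0.5, B1 = log(2)),
                   baseline_prevalence = 0.05, seed = 8)
  ph <- simulate_phenotypes(carrier, sp)
  # planted quantitative shift recovered
  expect_lt(abs(mean(ph$Q1[carrier]) - mean(ph$Q1[!carrier]) - 0.5), 0.1)
  # null trait balanced
  expect_lt(abs(mean(ph$Q2[carrier]) - mean(ph$Q2[!carrier])), 0.1)
  # planted log-odds ~ ln 2: logistic fit recovers OR near 2
  fit <- glm(ph$B1 ~ carrier, family = binomial())
  expect_lt(abs(exp(coef(fit)[2]) - 2), 0.5)
  # determinism
  expect_identical(simulate_phenotypes(carrier, sp), ph)
  expect_error(pheno_spec(n_binary = 1, baseline_prevalence = 0), "strictly")
  expect_error(pheno_spec(effect_map = c(Z9 = 1)), "subset")
})
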