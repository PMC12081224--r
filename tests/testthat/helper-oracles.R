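# Independent oracles and small fixtures used across the suite.

# Exhaustive minimum gain count: dynamic programming over bitmasks of the
# presence set, allowing a gain on any branch whose clade is entirely
# present. Independent of the package's maximal-subtree recursion.
brute_min_origins <- function(phy, present) {
  tips <- phy$tip.label
  p_tips <- tips[tips %in% present]
  np <- length(p_tips)
  if (np == 0) return(0L)
  if (np > 16) stop("oracle limited to 16 present tips")
  clade_sets <- lapply(seq_len(length(tips) + phy$Nnode), function(node) {
    if (node <= length(tips)) tips[node] else ape::extract.clade(phy, node)$tip.label
  })
  masks <- vapply(Filter(function(s) all(s %in% p_tips), clade_sets),
                  function(s) sum(2^(match(s, p_tips) - 1)), numeric(1))
  full <- 2^np - 1
  dp <- rep(Inf, full + 1)
  dp[1] <- 0
  for (m in 0:(full - 1)) {
    if (!is.finite(dp[m + 1])) next
    for (s in masks) {
      nm <- bitwOr(m, s)
      if (dp[nm + 1] > dp[m + 1] + 1) dp[nm + 1] <- dp[m + 1] + 1
    }
  }
  as.integer(dp[full + 1])
}

# Brute-force Benjamini-Hochberg: step-up rejection set and q-values.
brute_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  list(reject = reject, q = q[order(o)])
}

# Brute-force one-tailed Fisher p: enumerate every table with the observed
# margins and sum the probabilities of tables at least as extreme in the
# [1,1] cell, using factorial arithmetic only.
brute_fisher_onetail <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  lgp <- function(x) {
    b <- r1 - x; cc <- c1 - x; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(N - c1) -
      lfactorial(N) - lfactorial(x) - lfactorial(b) - lfactorial(cc) - lfactorial(d)
  }
  sup <- 0:min(r1, c1)
  probs <- vapply(sup, function(x) exp(lgp(x)), numeric(1))
  sum(probs[sup >= a]) / sum(probs)
}

toy_tree <- function(text) ape::read.tree(text = text)

reference_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "epar_haplogroup_tree.nwk",
                                   package = "eparscan"))
}

epar_carrier_haplogroups <- function() {
  c("E1a-M132", "I1a-Z58", "I1c-Z17954", "I2a-M223", "I2a-L233",
    "I2a-L1294", "K-M9", "R1b-L52", "R1b-U152", "R1b-CTS3655")
}

# Crossover coordinates that yield distinct junction sequences: one
# representative inside each gap between consecutive parental-difference
# positions (avoiding length-site interiors).
distinct_crossover_points <- function(model, n) {
  cat_ <- model$catalog
  diffpos <- sort(unique(cat_$pos[cat_$x_major != cat_$y_major]))
  gaps <- c(diffpos[1] - 5L, diffpos[-length(diffpos)] + 1L)
  bad <- unlist(lapply(model$length_sites, function(s) {
    seq(s$start + 1L, s$start + nchar(s$alleles[[1]]) - 1L)
  }))
  gaps <- gaps[!gaps %in% bad & gaps >= 1]
  if (length(gaps) < n) stop("not enough distinct junction classes available")
  gaps[seq_len(n)]
}
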