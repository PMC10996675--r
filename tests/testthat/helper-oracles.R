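# Independent oracles used to cross-check the package's statistics.

# Exhaustive all-pairs Kendall tau-b: enumerates every (i, j) pair and the
# tie groups directly.
oracle_tau_b <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1
        ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (sign(dx) == sign(dy)) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# Direct hypergeometric upper-tail summation for the one-sided Fisher test.
oracle_hyper_tail <- function(a, K, N, n) {
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Exhaustive placement enumeration for the rank-skew test: probability that
# m members randomly placed among N distinct ranks reach an ascending rank
# sum at least as large as the observed one.
oracle_rank_skew <- function(member_ranks_desc, N) {
  m <- length(member_ranks_desc)
  asc <- N + 1 - member_ranks_desc
  obs <- sum(asc)
  placements <- utils::combn(N, m)
  mean(colSums(placements) >= obs)
}

# A tiny deterministic study used across module tests: 2 genotypes + control,
# 3 replicates, features with hand-set values.
tiny_study <- function() {
  meta <- tibble::tibble(
    sample_id = c(paste0("control_r", 1:3), paste0("KO1_r", 1:3),
                  paste0("KO2_r", 1:3)),
    genotype = rep(c("control", "KO1", "KO2"), each = 3),
    replicate = rep(1:3, 3))
  crossome::validate_metadata(meta)
}

omics_tbl <- function(values, feature_ids, sample_ids, layer = "protein") {
  m <- matrix(values, nrow = length(feature_ids), byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  out <- tibble::as_tibble(as.data.frame(m))
  out <- tibble::tibble(feature_id = feature_ids, !!!out)
  attr(out, "layer") <- layer
  out
}
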