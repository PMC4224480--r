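# Small in-code fixtures shared across test files.

tinyMetaboSet <- function(n_features = 6, n_samples = 8, n_is = 1,
                          platform = "HILICpos", seed = 42) {
  set.seed(seed)
  fd <- data.frame(
    feature_id = paste0("M", 100 + seq_len(n_features), "T", 10 * seq_len(n_features)),
    mz = 100 + seq_len(n_features) + runif(n_features, 0, 0.2),
    rt_seconds = 10 * seq_len(n_features),
    platform = platform,
    is_internal_standard = c(rep(TRUE, n_is), rep(FALSE, n_features - n_is)))
  sd_ <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                    diagnosis = rep(c("case", "control"),
                                    length.out = n_samples))
  area <- matrix(rlnorm(n_features * n_samples, log(1e4), 0.3),
                 n_features, n_samples)
  MetaboSet(area, fd, sd_)
}

# brute-force BH step-up, independent of stats::p.adjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all-pairs AUC with ties counted 1/2
aucOracle <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels == "control"]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
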