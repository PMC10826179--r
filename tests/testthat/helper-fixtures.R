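# tiny on-disk fixtures, built in code at test time

write_tiny_ct_csv <- function(path = tempfile(fileext = ".csv"),
                              lines = c(
                                "mirna_id,S1,S2",
                                "miR-a,20,21",
                                "miR-b,30,",
                                "SPIKE_1,19,19.5"
                              )) {
  writeLines(lines, path)
  path
}

write_tiny_annotation_csv <- function(path = tempfile(fileext = ".csv"),
                                      lines = c("sample_id,class",
                                                "S1,RLN", "S2,nTFHL")) {
  writeLines(lines, path)
  path
}

write_tiny_gmt <- function(path = tempfile(fileext = ".gmt"),
                           lines = c("SETA\tdesc\tTP53\tMYC",
                                     "SETB\tdesc\tTP53\tEGFR\tKRAS")) {
  writeLines(lines, path)
  path
}

write_tiny_target_tsv <- function(path = tempfile(fileext = ".tsv"),
                                  rows = c(
                                    "miRTarBase ID\tmiRNA\tTarget Gene\tSupport Type",
                                    "MIRT000001\tmiR-1\tTP53\tFunctional MTI",
                                    "MIRT000002\tmiR-1\tMYC\tFunctional MTI (Weak)",
                                    "MIRT000003\tmiR-2\tEGFR\tFunctional MTI"
                                  )) {
  writeLines(rows, path)
  path
}

# small in-memory ct_matrix: 4 miRNAs + 1 spike-in, 4 samples
tiny_ct_matrix <- function(max_ct = 35) {
  ct <- rbind(
    "miR-a" = c(20, 21, 22, 23),
    "miR-b" = c(30, 31, 29, 30),
    "miR-c" = c(25, NA, NA, NA),
    "miR-d" = c(NA, NA, NA, NA),
    "SPIKE_1" = c(19, 20, 19, 21)
  )
  colnames(ct) <- paste0("S", 1:4)
  ct_matrix(ct, is_spike_in = c(FALSE, FALSE, FALSE, FALSE, TRUE), max_ct = max_ct)
}

# small fast cohort used across classification tests
small_cohort <- function(seed = 1, n_per_class = c(RLN = 10, nTFHL = 12, nPTCL = 10),
                         n_mirnas = 60, n_low_detection = 10, effects = NULL) {
  if (is.null(effects)) effects <- default_effects(n = 8)
  cohort_config(n_per_class = n_per_class, n_mirnas = n_mirnas,
                n_low_detection = n_low_detection, effects = effects,
                seed = seed)
}

# brute-force oracles -------------------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(ord == i)            # rank of p[i]
    tail <- ord[seq(j, n)]
    q[i] <- min(1, min(n * p[tail] / match(tail, ord)))
  }
  q
}

oracle_hyper_upper <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

oracle_ks_d <- function(x, y) {
  v <- sort(unique(c(x, y)))
  fx <- vapply(v, function(t) mean(x <= t), 0)
  fy <- vapply(v, function(t) mean(y <= t), 0)
  max(abs(fx - fy))
}
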