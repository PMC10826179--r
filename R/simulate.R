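#' Configuration for a synthetic FFPE miRNA qPCR cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a
#' three-class lymph-node cohort (19 reactive lymph nodes, 49 nTFHL, 20
#' nPTCL by default) profiled on a 376-miRNA panel of which ~130 miRNAs
#' have low detection rates, with spike-in control rows, per-sample
#' technical offsets, Gaussian within-class noise on the Ct scale, and
#' planted class effects. By default the planted signal consists of 22
#' effects shared by both lymphoma subtypes (half up-, half down-regulated,
#' |shift| 1-2 Ct), reflecting the strong expression similarity between the
#' two lymphoma entities; subtype-specific effects are opt-in.
#'
#' @param n_per_class Named or positional counts for (RLN, nTFHL, nPTCL).
#' @param n_mirnas Panel size excluding spike-ins (default 376).
#' @param n_low_detection Number of miRNAs given per-well dropout so their
#'   detection fraction stays below `detection_threshold` (default 130).
#' @param n_spike_ins Number of spike-in control rows (default 3).
#' @param baseline_ct_range Interval for per-miRNA baseline Ct (default
#'   `c(22, 32)`).
#' @param within_class_sd Biological + residual technical noise SD in Ct
#'   cycles (default 1.0).
#' @param technical_offset_sd SD of the per-sample additive technical
#'   offset in Ct cycles (default 0.5); removed by spike-in normalization.
#' @param effects Data frame with columns `mirna` (panel row index),
#'   `class` (`"nTFHL"`, `"nPTCL"` or `"both-lymphomas"`), `shift` (Ct
#'   cycles added to that class; negative shift = higher abundance =
#'   positive log2 fold change).
#' @param detection_threshold Detection fraction that low-detection rows
#'   must stay strictly below (default 0.10).
#' @param dropout_detect_prob Per-well probability that a low-detection
#'   miRNA amplifies at all (default 0.05).
#' @param max_ct Detection cutoff in cycles (default 35).
#' @param spike_in_ct Noise-free Ct of spike-in rows before the sample
#'   offset (default 20).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_class = c(RLN = 19, nTFHL = 49, nPTCL = 20),
                          n_mirnas = 376,
                          n_low_detection = 130,
                          n_spike_ins = 3,
                          baseline_ct_range = c(22, 32),
                          within_class_sd = 1.0,
                          technical_offset_sd = 0.5,
                          effects = default_effects(),
                          detection_threshold = 0.10,
                          dropout_detect_prob = 0.05,
                          max_ct = 35,
                          spike_in_ct = 20,
                          seed = 1L) {
  n_per_class <- setNames(as.integer(n_per_class), c("RLN", "nTFHL", "nPTCL"))
  if (any(n_per_class <= 0L)) stop_mp("class counts must be positive")
  stopifnot(n_mirnas >= 1, n_spike_ins >= 1,
            n_low_detection >= 0, n_low_detection < n_mirnas)
  if (!all(c("mirna", "class", "shift") %in% names(effects))) {
    stop_mp("`effects` needs columns mirna, class, shift")
  }
  if (any(!effects$class %in% c("nTFHL", "nPTCL", "both-lymphomas"))) {
    stop_mp("effect classes must be nTFHL, nPTCL or both-lymphomas")
  }
  if (any(effects$mirna < 1 | effects$mirna > n_mirnas)) {
    stop_mp("effect indices must lie within the panel (spike-in rows cannot carry effects)")
  }
  if (any(!is.finite(effects$shift))) stop_mp("effect shifts must be finite")
  structure(
    list(n_per_class = n_per_class, n_mirnas = n_mirnas,
         n_low_detection = n_low_detection, n_spike_ins = n_spike_ins,
         baseline_ct_range = baseline_ct_range,
         within_class_sd = within_class_sd,
         technical_offset_sd = technical_offset_sd,
         effects = effects, detection_threshold = detection_threshold,
         dropout_detect_prob = dropout_detect_prob,
         max_ct = max_ct, spike_in_ct = spike_in_ct,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default planted effects: 22 miRNAs deregulated in both lymphoma subtypes
#'
#' Shift magnitudes span 1.5-2.0 Ct with alternating sign (11 up- and 11
#' down-regulated in the lymphomas relative to RLN). The lower end is set
#' so that, at the default cohort sizes and noise level, every planted
#' effect is recoverable at q < 0.05 with near-certainty (weakest effect:
#' standardized difference 1.5 against a BH cutoff near |t| = 2.9, i.e.
#' per-effect detection probability above 99.8%) — the generator is a
#' recovery oracle, so its defaults must make the planted truth reliably
#' detectable, not borderline.
#'
#' @param n Number of shared effects (default 22).
#' @param shift_range Magnitude interval in Ct cycles (default
#'   `c(1.5, 2)`).
#' @return Effects data frame for [cohort_config()].
#' @export
default_effects <- function(n = 22, shift_range = c(1.5, 2)) {
  mag <- seq(shift_range[1], shift_range[2], length.out = n)
  data.frame(
    mirna = seq_len(n),
    class = rep("both-lymphomas", n),
    shift = mag * rep_len(c(-1, 1), n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic cohort
#'
#' Generates `ct(i, j) = baseline_i + class_shift(i, class_j) + offset_j +
#' noise` with Gaussian noise on the Ct scale, noise-free spike-in rows
#' (`spike_in_ct + offset_j`), and per-well dropout for the designated
#' low-detection miRNAs, rejection-resampled so each such miRNA's detected
#' fraction is below the configured threshold in every realization.
#' Low-detection rows are the last `n_low_detection` panel rows and must
#' not carry effects.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `ct` (a [ct_matrix] of
#'   `n_mirnas + n_spike_ins` rows by `sum(n_per_class)` samples),
#'   `annotation` (a `sample_annotation`) and `truth` (planted log2 fold
#'   changes per comparison, low-detection ids, per-sample offsets).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  low_idx <- if (cfg$n_low_detection > 0L) {
    seq(cfg$n_mirnas - cfg$n_low_detection + 1L, cfg$n_mirnas)
  } else integer(0)
  if (any(cfg$effects$mirna %in% low_idx)) {
    stop_mp("planted effects may not target low-detection miRNAs")
  }
  n <- sum(cfg$n_per_class)
  classes <- factor(rep(names(cfg$n_per_class), cfg$n_per_class),
                    levels = c("RLN", "nTFHL", "nPTCL"))
  sample_ids <- sprintf("S%03d", seq_len(n))
  mirna_ids <- sprintf("hsa-miR-sim-%04d", seq_len(cfg$n_mirnas))
  spike_ids <- sprintf("SPIKE_%d", seq_len(cfg$n_spike_ins))

  with_seed(cfg$seed, {
    baseline <- stats::runif(cfg$n_mirnas, cfg$baseline_ct_range[1],
                             cfg$baseline_ct_range[2])
    offset <- stats::rnorm(n, 0, cfg$technical_offset_sd)
    noise <- matrix(stats::rnorm(cfg$n_mirnas * n, 0, cfg$within_class_sd),
                    nrow = cfg$n_mirnas)
    shift <- matrix(0, nrow = cfg$n_mirnas, ncol = n)
    for (k in seq_len(nrow(cfg$effects))) {
      e <- cfg$effects[k, ]
      cols <- if (e$class == "both-lymphomas") classes != "RLN" else classes == e$class
      shift[e$mirna, cols] <- shift[e$mirna, cols] + e$shift
    }
    panel <- baseline + shift + rep(offset, each = cfg$n_mirnas) + noise
    panel <- pmin(pmax(panel, 0), 45)

    # per-well dropout for low-detection rows, guaranteed below threshold
    max_detected <- ceiling(cfg$detection_threshold * n) - 1L
    for (i in low_idx) {
      for (try in 1:1000) {
        keep <- stats::runif(n) < cfg$dropout_detect_prob
        det <- keep & panel[i, ] <= cfg$max_ct
        if (sum(det) <= max_detected) break
      }
      panel[i, !keep] <- NA_real_
    }

    spikes <- matrix(rep(cfg$spike_in_ct + offset, each = cfg$n_spike_ins),
                     nrow = cfg$n_spike_ins)
    full <- rbind(panel, spikes)
    dimnames(full) <- list(c(mirna_ids, spike_ids), sample_ids)
    m <- ct_matrix(full,
                   is_spike_in = c(rep(FALSE, cfg$n_mirnas),
                                   rep(TRUE, cfg$n_spike_ins)),
                   max_ct = cfg$max_ct)

    truth <- planted_truth(cfg, mirna_ids, low_idx, offset, sample_ids)
    list(ct = m,
         annotation = sample_annotation(sample_ids, as.character(classes)),
         truth = truth)
  })
}

# expected log2FC per comparison: -shift where planted; subtype-only
# effects appear diluted in the grouped lymphoma comparison
planted_truth <- function(cfg, mirna_ids, low_idx, offset, sample_ids) {
  log2fc <- matrix(0, nrow = cfg$n_mirnas, ncol = 3,
                   dimnames = list(mirna_ids, c("grouped", "nTFHL", "nPTCL")))
  w <- cfg$n_per_class[c("nTFHL", "nPTCL")] / sum(cfg$n_per_class[c("nTFHL", "nPTCL")])
  for (k in seq_len(nrow(cfg$effects))) {
    e <- cfg$effects[k, ]
    if (e$class == "both-lymphomas") {
      log2fc[e$mirna, ] <- log2fc[e$mirna, ] - e$shift
    } else {
      log2fc[e$mirna, e$class] <- log2fc[e$mirna, e$class] - e$shift
      log2fc[e$mirna, "grouped"] <- log2fc[e$mirna, "grouped"] - e$shift * w[[e$class]]
    }
  }
  list(log2fc = log2fc,
       low_detection_ids = mirna_ids[low_idx],
       effect_ids = mirna_ids[unique(cfg$effects$mirna)],
       sample_offsets = setNames(offset, sample_ids))
}

#' Simulate a miRNA-to-target-gene map
#'
#' Each miRNA receives a uniform-random number of targets in
#' `targets_per_mirna`, sampled without replacement from a shared gene
#' universe of size `n_genes`.
#'
#' @param n_mirnas Number of miRNAs (or supply `mirna_ids`).
#' @param n_genes Gene universe size; must be at least
#'   `max(targets_per_mirna)`.
#' @param targets_per_mirna Length-2 interval of target-set sizes
#'   (default `c(5, 30)`).
#' @param seed Integer seed.
#' @param mirna_ids Optional explicit miRNA ids.
#' @return A `target_map`.
#' @export
simulate_target_map <- function(n_mirnas, n_genes, targets_per_mirna = c(5, 30),
                                seed = 1L, mirna_ids = NULL) {
  if (is.null(mirna_ids)) mirna_ids <- sprintf("hsa-miR-sim-%04d", seq_len(n_mirnas))
  lo <- targets_per_mirna[1]; hi <- targets_per_mirna[2]
  if (lo < 1 || hi < lo) stop_mp("targets_per_mirna must be an interval with min >= 1")
  if (n_genes < hi) stop_mp("n_genes must be >= max(targets_per_mirna)")
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  with_seed(seed, {
    sizes <- lo + sample.int(hi - lo + 1L, length(mirna_ids), replace = TRUE) - 1L
    target_map(setNames(
      lapply(sizes, function(s) sample(genes, s)),
      mirna_ids
    ))
  })
}

#' Simulate gene-set collections with planted miRNA-target enrichment
#'
#' Null sets are drawn uniformly from the target-map gene universe. Each
#' planted set draws a fraction `strength` of its members from the union of
#' its source miRNAs' targets and the remainder uniformly from the rest of
#' the universe, so enrichment power scales with `strength`.
#'
#' @param map A `target_map` supplying the gene universe.
#' @param planted List of lists with fields `name`, `source_mirnas`
#'   (character, present in `map`), `strength` (in `[0, 1]`).
#' @param n_null_sets Number of uniform null sets.
#' @param set_size Length-2 interval of gene-set sizes (default
#'   `c(15, 25)`).
#' @param seed Integer seed.
#' @return A `gene_set_collection` whose universe is all target-map genes.
#' @export
simulate_gene_sets <- function(map, planted = list(), n_null_sets = 50,
                               set_size = c(15, 25), seed = 1L) {
  stopifnot(inherits(map, "target_map"))
  universe <- sort(unique(unlist(map, use.names = FALSE)))
  with_seed(seed, {
    sets <- list()
    for (p in planted) {
      if (is.null(p$name) || is.null(p$source_mirnas) || is.null(p$strength)) {
        stop_mp("each planted set needs name, source_mirnas, strength")
      }
      if (p$strength < 0 || p$strength > 1) stop_mp("enrichment strength must be in [0, 1]")
      missing <- setdiff(p$source_mirnas, names(map))
      if (length(missing) > 0L) {
        stop_mp("source miRNAs absent from target map: ", paste(missing, collapse = ", "))
      }
      size <- if (set_size[1] == set_size[2]) set_size[1] else sample(set_size[1]:set_size[2], 1L)
      pool <- unique(unlist(map[p$source_mirnas], use.names = FALSE))
      n_target <- min(round(p$strength * size), length(pool))
      from_targets <- sample(pool, n_target)
      rest <- sample(setdiff(universe, from_targets), size - n_target)
      sets[[p$name]] <- c(from_targets, rest)
    }
    for (k in seq_len(n_null_sets)) {
      size <- if (set_size[1] == set_size[2]) set_size[1] else sample(set_size[1]:set_size[2], 1L)
      sets[[sprintf("NULL_SET_%03d", k)]] <- sample(universe, size)
    }
    gene_set_collection(sets, universe = universe)
  })
}
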