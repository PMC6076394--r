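# Synthetic two-condition studies with planted metagene structure.
#
# The generator states a concrete world for the whole pipeline: sparse
# marker blocks in the basis, one dominant factor per sample in the
# coefficients (plus an always-on "program" factor in the two-condition
# study), Poisson or truncated-Gaussian noise around W %*% H, and an
# annotation table with the probe categories a spotted-oligo platform
# carries (gene symbols, cDNA clones, hypothetical proteins, non-human
# spots, obsolete probes, duplicate symbols).

.annotation_categories <- c("symbol", "cdna", "hypothetical", "non_human",
                            "obsolete")

.apply_noise <- function(lambda, noise_model, noise_scale) {
  if (noise_scale == 0) {
    return(lambda)
  }
  if (noise_model == "poisson") {
    # scaled Poisson: mean lambda, variance noise_scale * lambda
    X <- matrix(stats::rpois(length(lambda), lambda / noise_scale),
                nrow(lambda), ncol(lambda)) * noise_scale
  } else {
    X <- pmax(lambda + matrix(stats::rnorm(length(lambda), 0, noise_scale),
                              nrow(lambda), ncol(lambda)), 0)
  }
  X
}

# Build (W, H, X) given explicit per-factor marker gene sets.
#
# h_structure "cluster": each sample gets one dominant factor (round-robin,
# weight ~ U(1,2)) over a small uniform background — consensus-clusterable
# samples for rank selection.
#
# h_structure "program": factor 1 is the condition's expression program —
# the only strong factor (U(1, 2)) in the first m - (rank - 1) samples and
# weakly active (U(0.05, 0.3)) in every other sample of the condition;
# remaining samples each get one strong round-robin cluster factor. The
# exclusive samples keep the program's coefficient ray extremal in sample
# space, which is what makes the factor recoverable by NMF at the planted
# rank (a factor strongly expressed everywhere sits inside the cone spanned
# by the per-sample cluster rays and gets smeared across fitted factors,
# which we verified empirically on this generator); the weak tail gives
# every sample of the condition a small but estimable program weight.
#
# marker_signal: optional list parallel to marker_sets with per-gene signal
# magnitudes (defaults to `signal` for every marker).
.plant_factors <- function(gene_ids, n_samples, rank, marker_sets, signal,
                           baseline, noise_model, noise_scale, seed,
                           h_structure = c("cluster", "program"),
                           marker_signal = NULL, home = NULL,
                           bg_amplitude = NULL) {
  h_structure <- match.arg(h_structure)
  set.seed(seed)
  n_genes <- length(gene_ids)
  # Background genes are low-amplitude members of the same expression
  # programs (a "home" factor carries most of their loading): real
  # transcriptomes are modular, and unstructured background profiles fill
  # the interior of the factor cone and degrade identifiability. Module
  # membership and amplitude can be supplied so that they stay consistent
  # across the conditions of one study.
  if (is.null(home)) home <- sample.int(rank, n_genes, replace = TRUE)
  if (is.null(bg_amplitude)) {
    bg_amplitude <- stats::runif(n_genes, 0, baseline)
  }
  W <- matrix(stats::runif(n_genes * rank, 0.15, 0.5), n_genes, rank)
  W[cbind(seq_len(n_genes), home)] <- stats::runif(n_genes, 0.4, 0.8)
  W <- W / rowSums(W) * bg_amplitude * rank
  for (k in seq_len(rank)) {
    idx <- match(marker_sets[[k]], gene_ids)
    .assert(!anyNA(idx), "marker gene id not in gene universe")
    W[idx, ] <- baseline
    sig_k <- if (is.null(marker_signal)) signal else marker_signal[[k]]
    W[idx, k] <- sig_k
  }
  H <- matrix(stats::runif(rank * n_samples, 0, 0.1), rank, n_samples)
  if (h_structure == "program") {
    n_excl <- max(1L, n_samples - (rank - 1L))
    H[1L, seq_len(n_excl)] <- stats::runif(n_excl, 1, 2)
    if (rank >= 2L && n_samples > n_excl) {
      dom <- rep(seq_len(rank)[-1L], length.out = n_samples - n_excl)
      for (j in seq_len(n_samples - n_excl)) {
        H[dom[j], n_excl + j] <- stats::runif(1, 1, 2)
      }
    }
  } else {
    dom <- rep(seq_len(rank), length.out = n_samples)
    for (j in seq_len(n_samples)) H[dom[j], j] <- stats::runif(1, 1, 2)
  }
  rownames(W) <- gene_ids
  X <- .apply_noise(W %*% H, noise_model, noise_scale)
  rownames(X) <- gene_ids
  colnames(X) <- sprintf("sample%02d", seq_len(n_samples))
  colnames(W) <- paste0("metagene", seq_len(rank))
  dimnames(H) <- list(colnames(W), colnames(X))
  list(W = W, H = H, X = X)
}

#' Generate a nonnegative matrix with planted low-rank metagene structure
#'
#' Plants `rank` disjoint marker blocks of `markers_per_factor` genes: marker
#' rows carry `signal` on their factor and `baseline` elsewhere; non-marker
#' rows are i.i.d. uniform on `(0, baseline)`. Coefficient columns give each
#' sample one dominant factor (round-robin across factors, weight ~ U(1, 2))
#' over a small uniform background, so samples form consensus-clusterable
#' groups. The observed matrix is `clamp+(W %*% H + noise)` under the chosen
#' noise model; `noise_scale = 0` returns `W %*% H` exactly.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param rank number of planted factors.
#' @param markers_per_factor marker genes per factor
#'   (`rank * markers_per_factor <= n_genes`).
#' @param signal,baseline marker and background loading magnitudes
#'   (`signal >> baseline` gives sparse, block-like basis structure).
#' @param noise_model `"poisson"` (scaled Poisson counts around `W %*% H`,
#'   variance `noise_scale * mean`; the default, matching nonnegative
#'   heteroscedastic intensities) or `"truncated-gaussian"` (additive
#'   N(0, `noise_scale`) clamped at 0).
#' @param noise_scale nonnegative noise dial; 0 means noiseless.
#' @param seed integer seed; outputs are bitwise-reproducible.
#' @return A list with `X` (an [expression_matrix()]), `W_true`, `H_true`,
#'   `marker_sets` (list of gene-id character vectors, one per factor) and
#'   `seed`.
#' @export
generate_planted_matrix <- function(n_genes, n_samples, rank,
                                    markers_per_factor, signal = 10,
                                    baseline = 0.1,
                                    noise_model = c("poisson",
                                                    "truncated-gaussian"),
                                    noise_scale = 1, seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  n_samples <- .check_count(n_samples, "n_samples")
  rank <- .check_count(rank, "rank")
  markers_per_factor <- .check_count(markers_per_factor, "markers_per_factor")
  signal <- .check_scalar(signal, "signal", min = 0, strict_min = TRUE)
  baseline <- .check_scalar(baseline, "baseline", min = 0, strict_min = TRUE)
  noise_model <- match.arg(noise_model)
  noise_scale <- .check_scalar(noise_scale, "noise_scale", min = 0)
  .assert(rank * markers_per_factor <= n_genes,
          "rank * markers_per_factor exceeds n_genes")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  set.seed(.derive_seed(seed, 1L))
  marker_idx <- sample(n_genes, rank * markers_per_factor)
  marker_sets <- split(gene_ids[marker_idx],
                       rep(seq_len(rank), each = markers_per_factor))
  names(marker_sets) <- paste0("metagene", seq_len(rank))
  pl <- .plant_factors(gene_ids, n_samples, rank, marker_sets, signal,
                       baseline, noise_model, noise_scale,
                       .derive_seed(seed, 2L))
  list(X = expression_matrix(pl$X),
       W_true = pl$W, H_true = pl$H,
       marker_sets = marker_sets, seed = seed)
}

#' Generate a planted two-condition study
#'
#' Emulates a two-condition microarray design (defaults: 8 + 10 samples,
#' per-condition ranks 5 and 8 over ~2000 genes). Each condition carries a
#' condition-wide "program" factor (factor 1, expressed in every sample and
#' exclusively in a couple of them, keeping its coefficient ray extremal and
#' hence recoverable) plus round-robin cluster factors. Condition B's
#' program factor is the dominant one: its marker set is `shared_markers`
#' (planted in both conditions' program factors, a fraction
#' `shared_fraction` of the B set, induced at `shared_attenuation_a *
#' signal` in A) union `specific_markers_b` (planted nowhere in condition
#' A). The B program block is the largest planted block, modelling an
#' expression program acquired in the malignant condition that the
#' concatenated analysis should single out.
#'
#' @param n_genes gene-universe size (identical and identically ordered in
#'   both conditions).
#' @param m_a,m_b samples per condition.
#' @param rank_a,rank_b planted ranks per condition.
#' @param shared_fraction fraction of B's dominant marker set also planted in
#'   A's program factor.
#' @param markers_per_factor markers per non-dominant factor.
#' @param dominant_multiple_a,dominant_multiple_b the program factors carry
#'   `dominant_multiple_* * markers_per_factor` markers, making them the
#'   most informative metagenes of their conditions.
#' @param shared_attenuation_a multiplier on `signal` for shared markers in
#'   condition A's program factor (the shared program is induced more weakly
#'   in the premalignant condition).
#' @inheritParams generate_planted_matrix
#' @param frac_cdna,frac_hypothetical,frac_non_human,frac_obsolete,n_duplicate_symbols
#'   forwarded to [generate_annotation()].
#' @param label_a,label_b condition labels attached to the samples.
#' @return An object of class `planted_study`: `X_a`, `X_b`
#'   ([expression_matrix()]s), `W_true_a`, `H_true_a`, `W_true_b`,
#'   `H_true_b`, `marker_sets_a`, `marker_sets_b`, `shared_markers`,
#'   `specific_markers_b`, `dominant_factor_a`, `dominant_factor_b` (both 1),
#'   `annotation`, `seed`, `params`.
#' @export
generate_two_condition_study <- function(n_genes = 2000L, m_a = 8L, m_b = 10L,
                                         rank_a = 5L, rank_b = 8L,
                                         shared_fraction = 0.1,
                                         markers_per_factor = 50L,
                                         dominant_multiple_a = 2L,
                                         dominant_multiple_b = 5L,
                                         signal = 1000, baseline = 10,
                                         shared_attenuation_a = 0.5,
                                         noise_model = c("poisson",
                                                         "truncated-gaussian"),
                                         noise_scale = 1,
                                         frac_cdna = 0.32,
                                         frac_hypothetical = 0.08,
                                         frac_non_human = 0.07,
                                         frac_obsolete = 0.03,
                                         n_duplicate_symbols = 20L,
                                         label_a = "MGUS", label_b = "MM",
                                         seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  m_a <- .check_count(m_a, "m_a"); m_b <- .check_count(m_b, "m_b")
  rank_a <- .check_count(rank_a, "rank_a", min = 2L)
  rank_b <- .check_count(rank_b, "rank_b", min = 2L)
  shared_fraction <- .check_proportion(shared_fraction, "shared_fraction")
  markers_per_factor <- .check_count(markers_per_factor, "markers_per_factor")
  dominant_multiple_a <- .check_count(dominant_multiple_a, "dominant_multiple_a")
  dominant_multiple_b <- .check_count(dominant_multiple_b, "dominant_multiple_b")
  shared_attenuation_a <- .check_scalar(shared_attenuation_a,
                                        "shared_attenuation_a", min = 0,
                                        strict_min = TRUE)
  noise_model <- match.arg(noise_model)

  n_dom_b <- dominant_multiple_b * markers_per_factor
  n_shared <- round(shared_fraction * n_dom_b)
  # A's program factor grows if needed so that every shared marker is also
  # one of its markers (relevant only for extreme shared fractions)
  n_dom_a <- max(dominant_multiple_a * markers_per_factor, n_shared)
  n_spec_b <- n_dom_b - n_shared
  # Conditions share their non-dominant co-expression modules (housekeeping
  # programs active in both disease stages); condition B additionally
  # carries weak idiosyncratic modules when rank_b > rank_a. The shared
  # modules keep the concatenated matrix close to rank_a effective
  # structures, the regime the concatenated fit assumes.
  n_modules <- min(rank_a, rank_b) - 1L
  n_extra_a <- rank_a - 1L - n_modules
  n_extra_b <- rank_b - 1L - n_modules
  n_need <- n_dom_a + n_spec_b +
    (n_modules + n_extra_a + n_extra_b) * markers_per_factor
  .assert(n_need <= n_genes,
          sprintf("marker demand (%d genes) exceeds n_genes (%d)", n_need,
                  n_genes))

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  set.seed(.derive_seed(seed, 11L))
  pool <- sample(gene_ids, n_need)
  take <- function(k) {
    if (k == 0L) return(character(0)) # pool[-integer(0)] would drop everything
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  shared <- if (n_shared > 0L) take(n_shared) else character(0)
  dom_a <- c(shared, take(n_dom_a - n_shared))
  modules <- lapply(seq_len(n_modules), function(i) take(markers_per_factor))
  marker_sets_a <- c(list(dom_a), modules,
                     lapply(seq_len(n_extra_a),
                            function(i) take(markers_per_factor)))
  specific_b <- if (n_spec_b > 0L) take(n_spec_b) else character(0)
  dom_b <- c(shared, specific_b)
  marker_sets_b <- c(list(dom_b), modules,
                     lapply(seq_len(n_extra_b),
                            function(i) take(markers_per_factor)))
  names(marker_sets_a) <- paste0("metagene", seq_len(rank_a))
  names(marker_sets_b) <- paste0("metagene", seq_len(rank_b))

  # Shared program genes are induced in both conditions but more strongly in
  # condition B (attenuation 0.5 in A): the activation program intensifies
  # in the malignant condition, and the concatenated fit then assigns shared
  # genes to the B program rather than splitting them arbitrarily.
  marker_signal_a <- c(list(c(rep(shared_attenuation_a * signal, n_shared),
                              rep(signal, n_dom_a - n_shared))),
                       rep(list(signal), rank_a - 1L))
  # B's idiosyncratic extra modules are weak (0.2 * signal): minor programs,
  # not competitors of the disease program.
  marker_signal_b <- c(rep(list(signal), 1L + n_modules),
                       rep(list(0.2 * signal), n_extra_b))
  # Module membership and baseline amplitude are gene properties, drawn once
  # per study: background genes keep the same (shared-module) home in both
  # conditions, so their concatenated profiles stay single-factor.
  set.seed(.derive_seed(seed, 15L))
  home <- sample(1L + seq_len(n_modules), n_genes, replace = TRUE)
  bg_amplitude <- stats::runif(n_genes, 0, baseline)
  pa <- .plant_factors(gene_ids, m_a, rank_a, marker_sets_a, signal, baseline,
                       noise_model, noise_scale, .derive_seed(seed, 12L),
                       h_structure = "program",
                       marker_signal = marker_signal_a,
                       home = home, bg_amplitude = bg_amplitude)
  pb <- .plant_factors(gene_ids, m_b, rank_b, marker_sets_b, signal, baseline,
                       noise_model, noise_scale, .derive_seed(seed, 13L),
                       h_structure = "program",
                       marker_signal = marker_signal_b,
                       home = home, bg_amplitude = bg_amplitude)
  ann <- generate_annotation(gene_ids, frac_cdna = frac_cdna,
                             frac_hypothetical = frac_hypothetical,
                             frac_non_human = frac_non_human,
                             frac_obsolete = frac_obsolete,
                             n_duplicate_symbols = n_duplicate_symbols,
                             seed = .derive_seed(seed, 14L))
  xa <- expression_matrix(pa$X,
                          sample_ids = sprintf("%s_%02d", label_a, seq_len(m_a)),
                          condition = rep(label_a, m_a))
  xb <- expression_matrix(pb$X,
                          sample_ids = sprintf("%s_%02d", label_b, seq_len(m_b)),
                          condition = rep(label_b, m_b))
  structure(list(X_a = xa, X_b = xb,
                 W_true_a = pa$W, H_true_a = pa$H,
                 W_true_b = pb$W, H_true_b = pb$H,
                 marker_sets_a = marker_sets_a,
                 marker_sets_b = marker_sets_b,
                 shared_markers = shared,
                 specific_markers_b = specific_b,
                 dominant_factor_a = 1L, dominant_factor_b = 1L,
                 annotation = ann, seed = seed,
                 params = list(n_genes = n_genes, m_a = m_a, m_b = m_b,
                               rank_a = rank_a, rank_b = rank_b,
                               shared_fraction = shared_fraction,
                               markers_per_factor = markers_per_factor,
                               dominant_multiple_a = dominant_multiple_a,
                               dominant_multiple_b = dominant_multiple_b,
                               shared_attenuation_a = shared_attenuation_a,
                               signal = signal, baseline = baseline,
                               noise_model = noise_model,
                               noise_scale = noise_scale,
                               label_a = label_a, label_b = label_b)),
            class = "planted_study")
}

#' @export
print.planted_study <- function(x, ...) {
  cat(sprintf("planted_study: %d genes; %s %d samples (rank %d), %s %d samples (rank %d)\n",
              x$params$n_genes, x$params$label_a, x$params$m_a,
              x$params$rank_a, x$params$label_b, x$params$m_b, x$params$rank_b))
  cat(sprintf("  shared markers %d, %s-specific markers %d, seed %d\n",
              length(x$shared_markers), x$params$label_b,
              length(x$specific_markers_b), x$seed))
  invisible(x)
}

#' Generate a probe annotation table
#'
#' Assigns each probe one of the categories `cdna` ("Homo sapiens cDNA"),
#' `hypothetical` ("hypothetical protein"), `non_human`, `obsolete`, or
#' `symbol` (the remainder, with a gene-symbol string). Category counts are
#' the rounded fractions of the probe count. Exactly `n_duplicate_symbols`
#' symbol-category probes share their symbol with another probe (duplicates
#' are formed as pairs, plus one triple when the count is odd; a count of 1
#' is therefore impossible and rejected).
#'
#' @param gene_ids character vector of probe ids.
#' @param frac_cdna,frac_hypothetical,frac_non_human,frac_obsolete category
#'   fractions; must sum to at most 1.
#' @param n_duplicate_symbols number of symbol-category probes with a
#'   non-unique symbol (0 or >= 2).
#' @param seed integer seed.
#' @return A data.frame with columns `probe_id`, `symbol` (`NA` outside the
#'   symbol category), `category`.
#' @export
generate_annotation <- function(gene_ids, frac_cdna = 0,
                                frac_hypothetical = 0, frac_non_human = 0,
                                frac_obsolete = 0, n_duplicate_symbols = 0L,
                                seed = 1L) {
  gene_ids <- as.character(gene_ids)
  .assert(!anyDuplicated(gene_ids), "duplicate probe ids")
  fr <- c(cdna = .check_proportion(frac_cdna, "frac_cdna"),
          hypothetical = .check_proportion(frac_hypothetical,
                                           "frac_hypothetical"),
          non_human = .check_proportion(frac_non_human, "frac_non_human"),
          obsolete = .check_proportion(frac_obsolete, "frac_obsolete"))
  .assert(sum(fr) <= 1, "category fractions sum above 1")
  n_duplicate_symbols <- .check_count(n_duplicate_symbols,
                                      "n_duplicate_symbols", min = 0L)
  .assert(n_duplicate_symbols != 1L,
          "a single probe cannot share a symbol; use 0 or >= 2")
  n <- length(gene_ids)
  counts <- round(fr * n)
  n_symbol <- n - sum(counts)
  .assert(n_symbol >= 0, "rounded category counts exceed the probe count")
  .assert(n_duplicate_symbols <= n_symbol,
          "n_duplicate_symbols exceeds the number of symbol-category probes")
  set.seed(seed)
  perm <- sample.int(n)
  category <- rep("symbol", n)
  offset <- 0L
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k > 0L) category[perm[offset + seq_len(k)]] <- nm
    offset <- offset + k
  }
  symbol <- rep(NA_character_, n)
  sym_idx <- perm[offset + seq_len(n_symbol)]
  if (n_symbol > 0L) {
    symbol[sym_idx] <- sprintf("SYM%05d", seq_len(n_symbol))
  }
  if (n_duplicate_symbols >= 2L) {
    dup_idx <- sym_idx[seq_len(n_duplicate_symbols)]
    # groups of 2; a trailing group of 3 when the count is odd
    sizes <- rep(2L, n_duplicate_symbols %/% 2L)
    if (n_duplicate_symbols %% 2L == 1L) {
      sizes[length(sizes)] <- 3L
    }
    g <- rep(seq_along(sizes), times = sizes)
    symbol[dup_idx] <- sprintf("DUP%04d", g)
  }
  data.frame(probe_id = gene_ids, symbol = symbol, category = category,
             stringsAsFactors = FALSE)
}
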