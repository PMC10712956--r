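#' Simulate a sub-mitochondrial fractionation experiment
#'
#' Forward model of the two-step MTY label-recovery assay. A common
#' labelled mitochondrial pool is split twice: digitonin treatment
#' separates mitoplasts (pellet) from the outer-membrane/IMS fraction
#' (supernatant), and sonication of the mitoplasts separates 'inside-out'
#' sub-mitochondrial particles (SMP pellet) from the matrix supernatant.
#' Each fraction's labelled reading is `retention * pool` (or the
#' complement) plus that fraction's autofluorescence plus noise; the paired
#' unlabelled (blank) reading is autofluorescence plus noise. Noise is
#' Gaussian with SD equal to `noise_sd` times the reading's true mean.
#'
#' @param retention_mitoplast Proportion of label retained in the mitoplast
#'   pellet at the first split (0-1).
#' @param retention_smp Proportion of the mitoplast label retained in the
#'   SMP pellet at the second split (0-1).
#' @param autofluorescence Named numeric autofluorescence per fraction, AU;
#'   names `mitoplast_pellet`, `om_ims_supernatant`, `smp_pellet`,
#'   `matrix_supernatant`.
#' @param pool Total labelled fluorescence entering the first split, AU.
#' @param noise_sd Relative noise (fraction of each reading's mean).
#' @param n_trials Number of independent trials (>= 1).
#' @param seed Integer seed.
#' @return An object of class `fractionation_experiment`: a data frame
#'   with columns `trial`, `split` (`"mitoplast"`/`"smp"`), `fraction`
#'   (`"pellet"`/`"supernatant"`), `labelled`, `unlabelled`.
#' @export
simulate_fractionation <- function(retention_mitoplast = 0.92,
                                   retention_smp = 0.90,
                                   autofluorescence = c(mitoplast_pellet = 80,
                                                        om_ims_supernatant = 40,
                                                        smp_pellet = 70,
                                                        matrix_supernatant = 40),
                                   pool = 1000, noise_sd = 0,
                                   n_trials = 2, seed = NULL) {
  for (r in c(retention_mitoplast, retention_smp)) {
    if (!is_number(r) || r < 0 || r > 1) {
      abort_validation("retentions must lie in [0, 1]")
    }
  }
  if (!is_number(n_trials) || n_trials < 1) abort_validation("n_trials must be >= 1")
  if (!is_number(noise_sd) || noise_sd < 0) abort_validation("noise_sd must be >= 0")
  need <- c("mitoplast_pellet", "om_ims_supernatant", "smp_pellet",
            "matrix_supernatant")
  if (!all(need %in% names(autofluorescence))) {
    abort_validation(sprintf("autofluorescence must be named: %s",
                             paste(need, collapse = ", ")))
  }
  a <- autofluorescence
  pool2 <- retention_mitoplast * pool  # label entering the sonication split
  mu <- data.frame(
    split = rep(c("mitoplast", "mitoplast", "smp", "smp"), n_trials),
    fraction = rep(c("pellet", "supernatant"), 2 * n_trials),
    labelled_mu = rep(c(retention_mitoplast * pool + a[["mitoplast_pellet"]],
                        (1 - retention_mitoplast) * pool + a[["om_ims_supernatant"]],
                        retention_smp * pool2 + a[["smp_pellet"]],
                        (1 - retention_smp) * pool2 + a[["matrix_supernatant"]]),
                      n_trials),
    unlabelled_mu = rep(a[need], n_trials),
    trial = rep(seq_len(n_trials), each = 4L)
  )
  n <- nrow(mu)
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(2L * n))
  } else rep(0, 2L * n)
  out <- data.frame(
    trial = mu$trial, split = mu$split, fraction = mu$fraction,
    labelled = mu$labelled_mu * (1 + noise_sd * eps[seq_len(n)]),
    unlabelled = mu$unlabelled_mu * (1 + noise_sd * eps[n + seq_len(n)])
  )
  if (any(out$labelled < 0) || any(out$unlabelled < 0)) {
    abort_validation("simulated fluorescence reading < 0: noise too large")
  }
  class(out) <- c("fractionation_experiment", "data.frame")
  out
}

#' Autofluorescence-corrected label-recovery proportions
#'
#' For each split (pellet vs supernatant pair) and trial, the blank
#' (unlabelled) reading is subtracted from the labelled reading of the
#' corresponding fraction, and the retained proportion is the corrected
#' pellet signal over the corrected pellet + supernatant total. The mean
#' over trials is reported as a percentage; the SD is reported only with
#' three or more trials. A corrected signal below zero (autofluorescence
#' exceeding the labelled reading) is an error, as is a zero denominator.
#'
#' @param expt A `fractionation_experiment` (from
#'   [simulate_fractionation()] or [read_fractionation_table()]).
#' @return An object of class `recovery_proportions`: data frame with one
#'   row per split (`split`, `mean_percent`, `sd_percent`, `n_trials`);
#'   attribute `per_trial` holds the per-trial percentages.
#' @examples
#' e <- simulate_fractionation(0.92, 0.90, noise_sd = 0, n_trials = 2)
#' recovery_proportions(e)
#' @export
recovery_proportions <- function(expt) {
  if (!is.data.frame(expt) ||
      !all(c("trial", "split", "fraction", "labelled", "unlabelled") %in% names(expt))) {
    abort_validation("expt must have columns trial, split, fraction, labelled, unlabelled")
  }
  expt$corrected <- expt$labelled - expt$unlabelled
  if (any(expt$corrected < 0)) {
    abort_validation("autofluorescence exceeds labelled signal in at least one fraction")
  }
  per_trial <- list()
  out <- data.frame(split = character(0), mean_percent = numeric(0),
                    sd_percent = numeric(0), n_trials = integer(0))
  for (s in unique(expt$split)) {
    vals <- numeric(0)
    for (tr in unique(expt$trial[expt$split == s])) {
      sub <- expt[expt$split == s & expt$trial == tr, ]
      pel <- sub$corrected[sub$fraction == "pellet"]
      sup <- sub$corrected[sub$fraction == "supernatant"]
      if (length(pel) != 1L || length(sup) != 1L) {
        abort_validation(sprintf("split '%s' trial %s lacks a paired pellet/supernatant", s, tr))
      }
      denom <- pel + sup
      if (denom == 0) abort_validation("zero corrected total: proportion undefined")
      vals <- c(vals, 100 * pel / denom)
    }
    per_trial[[s]] <- vals
    out <- rbind(out, data.frame(
      split = s, mean_percent = mean(vals),
      sd_percent = if (length(vals) >= 3) stats::sd(vals) else NA_real_,
      n_trials = length(vals)
    ))
  }
  attr(out, "per_trial") <- per_trial
  class(out) <- c("recovery_proportions", "data.frame")
  out
}

#' Read a fractionation table
#'
#' Reads a delimited table with columns `trial`, `fraction`, `labelled_AU`,
#' `unlabelled_AU`, where `fraction` is one of `mitoplast_pellet`,
#' `om_ims_supernatant`, `smp_pellet`, `matrix_supernatant`, and maps it
#' onto the split/pellet-supernatant layout used by
#' [recovery_proportions()].
#'
#' @param path File path (tab- or comma-delimited, `#` comments allowed).
#' @return A `fractionation_experiment` data frame.
#' @export
read_fractionation_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, comment.char = "#", sep = "",
                           stringsAsFactors = FALSE)
  need <- c("trial", "fraction", "labelled_AU", "unlabelled_AU")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort_validation(sprintf("missing required column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  map <- c(mitoplast_pellet = "mitoplast.pellet",
           om_ims_supernatant = "mitoplast.supernatant",
           smp_pellet = "smp.pellet",
           matrix_supernatant = "smp.supernatant")
  if (!all(tab$fraction %in% names(map))) {
    abort_validation(sprintf("unknown fraction label(s): %s",
                             paste(setdiff(tab$fraction, names(map)), collapse = ", ")))
  }
  parts <- strsplit(unname(map[tab$fraction]), ".", fixed = TRUE)
  out <- data.frame(
    trial = tab$trial,
    split = vapply(parts, `[`, character(1), 1L),
    fraction = vapply(parts, `[`, character(1), 2L),
    labelled = tab$labelled_AU,
    unlabelled = tab$unlabelled_AU
  )
  class(out) <- c("fractionation_experiment", "data.frame")
  out
}
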