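# Synthetic cohorts: per-group marker distributions parameterised by
# median and range, plus clinical covariates, with the group definitions
# (classifier cutoffs, calcification, perituberal zeros) built in.

# (median, low, high) triples per group for each quantified feature.
# Tuber-group and control values follow the published cohort summaries;
# SMI32 and vimentin (dysmorphic-neuron and giant-cell densities) have no
# published per-group summaries and use the package's own calibration,
# chosen to respect the subtype definitions: type A at or below both
# cutoffs (<=10 giant cells/mm2, <=3 dysmorphic/mm2), types B and C above,
# with C the giant-cell-rich, calcified extreme.
default_feature_params <- function() {
  trip <- function(m, l, h) c(median = m, low = l, high = h)
  list(
    ps6_pct = list(A = trip(1.73, 0.84, 4.09), B = trip(1.53, 0.63, 6.64),
                   C = trip(4.14, 0.88, 6.82),
                   perituberal = trip(0.70, 0.44, 3.64),
                   control = trip(0.18, 0.03, 0.67)),
    neun_density = list(A = trip(261.20, 106.56, 296.26),
                        B = trip(139.18, 32.03, 258.29),
                        C = trip(175.88, 55.70, 277.31),
                        perituberal = trip(256.63, 126.69, 459.07),
                        control = trip(351.39, 275.69, 540.46)),
    gfap_pct = list(A = trip(16.87, 1.01, 44.41), B = trip(18.34, 8.16, 34.06),
                    C = trip(13.87, 7.09, 34.02),
                    perituberal = trip(5.89, 2.15, 12.78),
                    control = trip(5.61, 2.25, 9.34)),
    cd3_density = list(A = trip(7.70, 4.23, 19.32), B = trip(13.81, 7.38, 35.85),
                       C = trip(22.64, 7.29, 34.20),
                       perituberal = trip(9.08, 1.91, 13.55),
                       control = trip(5.54, 0.56, 29.76)),
    cr343_pct = list(A = trip(3.10, 0.21, 7.63), B = trip(2.16, 0.25, 33.24),
                     C = trip(5.14, 0.26, 11.66),
                     perituberal = trip(0.95, 0.11, 2.50),
                     control = trip(0.51, 0.07, 1.70)),
    cd34_density = list(A = trip(73.85, 36.65, 169.35),
                        B = trip(73.90, 40.06, 190.45),
                        C = trip(114.48, 77.57, 154.12),
                        perituberal = trip(66.93, 28.49, 114.06),
                        control = trip(130.41, 36.77, 239.79)),
    omc = list(A = trip(389.95, 161.97, 3185.74),
               B = trip(196.23, 0.24, 8110.52),
               C = trip(273.46, 0.01, 3168.69),
               perituberal = trip(2711.58, 909.27, 6869.83),
               control = trip(2801.68, 188.05, 5815.44)),
    olig2_density = list(A = trip(159.22, 9.51, 405.16),
                         B = trip(103.03, 20.51, 390.42),
                         C = trip(133.31, 66.73, 832.46),
                         perituberal = trip(184.98, 109.86, 334.99),
                         control = trip(208.17, 88.01, 522.37)),
    smi32_density = list(A = trip(1, 0.2, 3), B = trip(6, 3.2, 12),
                         C = trip(25, 12, 50),
                         perituberal = trip(0, 0, 0),
                         control = trip(0, 0, 0)),
    vimentin_density = list(A = trip(4, 1, 10), B = trip(30, 12, 70),
                            C = trip(120, 60, 250),
                            perituberal = trip(0, 0, 0),
                            control = trip(0, 0, 0))
  )
}

#' Cohort specification
#'
#' Describes a synthetic study cohort: group sizes, per-group feature
#' distributions as (median, low, high) triples, the set of left-skewed
#' features (drawn on a log scale), and per-group calcification
#' probability — definitionally 1 for type C and 0 elsewhere, since
#' calcification is the discriminator that defines type C.
#'
#' @param n_per_group named integer vector over
#'   `c("A", "B", "C", "perituberal", "control")`; the default mirrors a
#'   realistic surgical series (7 / 13 / 8 tubers, 7 perituberal,
#'   6 controls).
#' @param feature_params nested list `feature -> group -> (median, low,
#'   high)`; see `default_feature_params` in the package source for the
#'   defaults.
#' @param skewed_features features drawn from a log-scale distribution;
#'   default pS6, SMI32 and vimentin, the left-skewed markers.
#' @param calcification_prob named probability per group.
#' @param seed default seed used when \code{\link{sample_cohort}} is called
#'   without one.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(A = 7L, B = 13L, C = 8L,
                                        perituberal = 7L, control = 6L),
                        feature_params = default_feature_params(),
                        skewed_features = c("ps6_pct", "smi32_density",
                                            "vimentin_density"),
                        calcification_prob = c(A = 0, B = 0, C = 1,
                                               perituberal = 0, control = 0),
                        seed = 1L) {
  groups <- c("A", "B", "C", "perituberal", "control")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name all of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  if (any(n_per_group < 0))
    stop("group sizes must be nonnegative", call. = FALSE)
  for (f in names(feature_params)) for (g in names(feature_params[[f]])) {
    p <- feature_params[[f]][[g]]
    if (!(p["low"] <= p["median"] && p["median"] <= p["high"]))
      stop(sprintf("feature %s, group %s: need low <= median <= high", f, g),
           call. = FALSE)
  }
  structure(list(n_per_group = n_per_group[groups],
                 feature_params = feature_params,
                 skewed_features = skewed_features,
                 calcification_prob = calcification_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-scale draw with exact population median m: lognormal with
# meanlog = log(m), sdlog spanning [low, high] as the central 95% band,
# clipped to [low, high] (clipping moves only tail mass, median unchanged)
draw_skewed <- function(n, m, low, high) {
  if (m <= 0) return(rep(0, n))
  sdlog <- if (high > low && low > 0)
    (log(high) - log(low)) / (2 * qnorm(0.975))
  else 0
  pmin(high, pmax(low, rlnorm(n, meanlog = log(m), sdlog = sdlog)))
}

# symmetric draw centred on the median, clipped to [low, high]
draw_symmetric <- function(n, m, low, high) {
  s <- (high - low) / (2 * qnorm(0.975))
  pmin(high, pmax(low, rnorm(n, mean = m, sd = s)))
}

#' Sample a synthetic cohort
#'
#' Draws one sample table from a \code{\link{cohort_spec}}. Skewed features
#' come from a log-scale distribution whose population median equals the
#' configured median and whose central ~95% band matches `[low, high]`;
#' the other features come from a clipped symmetric distribution. Group
#' structure is enforced exactly: type A draws satisfy both classifier
#' bounds (vimentin <= 10/mm2 and SMI32 <= 3/mm2), type B draws violate at
#' least one, type C samples additionally carry calcification, and
#' perituberal/control samples have zero giant cells and dysmorphic
#' neurons. Clinical covariates (age at surgery, epilepsy duration, AED
#' count, FCD-like imaging features, Engel outcome) are synthetic, with
#' epilepsy duration never exceeding age.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer; defaults to `spec$seed`.
#' @return data.frame, one row per sample: `sample_id`, `true_group`, the
#'   ten quantified features, `calcification_present`, and the clinical
#'   covariates.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  age_params <- list(A = c(10, 3, 47), B = c(7, 0.83, 22), C = c(3, 1, 6),
                     perituberal = c(8, 1, 47), control = c(8, 1, 47))
  fcd_prob <- c(A = 0.15, B = 0.65, C = 0.65, perituberal = 0.1, control = 0)
  rows <- list()
  for (g in names(spec$n_per_group)) {
    n <- spec$n_per_group[[g]]
    if (n == 0L) next
    feats <- lapply(names(spec$feature_params), function(f) {
      p <- spec$feature_params[[f]][[g]]
      if (f %in% spec$skewed_features)
        draw_skewed(n, p["median"], p["low"], p["high"])
      else
        draw_symmetric(n, p["median"], p["low"], p["high"])
    })
    names(feats) <- names(spec$feature_params)
    if (g == "A") {
      feats$vimentin_density <- pmin(feats$vimentin_density, 10)
      feats$smi32_density <- pmin(feats$smi32_density, 3)
    } else if (g %in% c("B", "C")) {
      # subtype definition: at least one density above its cutoff
      bad <- feats$vimentin_density <= 10 & feats$smi32_density <= 3
      tries <- 0L
      while (any(bad)) {
        tries <- tries + 1L
        if (tries > 1000L)
          stop(sprintf(
            "group %s parameters cannot satisfy its subtype definition", g),
            call. = FALSE)
        p <- spec$feature_params$vimentin_density[[g]]
        feats$vimentin_density[bad] <-
          draw_skewed(sum(bad), p["median"], p["low"], p["high"])
        p <- spec$feature_params$smi32_density[[g]]
        feats$smi32_density[bad] <-
          draw_skewed(sum(bad), p["median"], p["low"], p["high"])
        bad <- feats$vimentin_density <= 10 & feats$smi32_density <= 3
      }
    } else {
      feats$vimentin_density <- rep(0, n)
      feats$smi32_density <- rep(0, n)
    }
    ap <- age_params[[g]]
    age <- draw_skewed(n, ap[1], ap[2], ap[3])
    rows[[g]] <- data.frame(
      sample_id = sprintf("%s%02d", g, seq_len(n)),
      true_group = g,
      as.data.frame(feats),
      calcification_present =
        runif(n) < spec$calcification_prob[[g]],
      age_at_surgery_y = age,
      epilepsy_duration_y = age * runif(n, 0.2, 0.9),
      aed_count = if (g == "A") sample(1:2, n, replace = TRUE)
                  else if (g == "control") rep(0L, n)
                  else sample(1:5, n, replace = TRUE),
      fcd_like = runif(n) < fcd_prob[[g]],
      engel = sample(1:4, n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.1, 0.1)),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
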