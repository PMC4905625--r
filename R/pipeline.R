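# Run orchestration: generation -> quantification -> classification ->
# clustering -> statistics, with a manifest for reproducibility.

#' Run configuration
#'
#' Bundles every tunable of a pipeline run. All defaults equal the
#' published analysis parameters: detection thresholds and size gates from
#' \code{\link{default_marker_panel}}, classifier cutoffs 10 and 3
#' cells/mm2, the three clustering features with the 1e-3 log offset and a
#' 3-cluster cut, and 1000 bootstrap resamples at the 95% level.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for run artifacts.
#' @param cohort a \code{\link{cohort_spec}} used in simulate mode.
#' @param panel marker panel (list of \code{\link{marker_config}}).
#' @param gc_cutoff,dn_cutoff classifier cutoffs (cells/mm2).
#' @param cluster_features feature columns used for clustering.
#' @param k cluster count, or `NULL` for automatic selection.
#' @param epsilon log-transform offset.
#' @param bootstrap_B,bootstrap_level BCa bootstrap settings.
#' @param n_phantoms number of phantom slides rendered and quantified in
#'   the quantification stage (0 disables the stage).
#' @param phantom_px phantom side length in pixels.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("tuberquant_run_"),
                       cohort = cohort_spec(),
                       panel = default_marker_panel(),
                       gc_cutoff = 10, dn_cutoff = 3,
                       cluster_features = c("ps6_pct", "smi32_density",
                                            "vimentin_density"),
                       k = 3L, epsilon = 1e-3,
                       bootstrap_B = 1000L, bootstrap_level = 0.95,
                       n_phantoms = 2L, phantom_px = 192L) {
  if (gc_cutoff <= 0 || dn_cutoff <= 0)
    stop("classifier cutoffs must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, panel = panel, gc_cutoff = gc_cutoff,
                 dn_cutoff = dn_cutoff, cluster_features = cluster_features,
                 k = k, epsilon = epsilon, bootstrap_B = bootstrap_B,
                 bootstrap_level = bootstrap_level,
                 n_phantoms = as.integer(n_phantoms),
                 phantom_px = as.integer(phantom_px)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the \code{\link{run_config}}
#' arguments; `panel` entries are lists with `name`, `blue_threshold`,
#' `min_area_px`, `max_area_px` (string "unlimited" or absent means
#' unbounded) and `mode`; `cohort` holds `n_per_group` and optional
#' `calcification_prob`. Absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("seed", "out_dir", "gc_cutoff", "dn_cutoff",
                "cluster_features", "k", "epsilon", "bootstrap_B",
                "bootstrap_level", "n_phantoms", "phantom_px"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$panel)) {
    args$panel <- lapply(y$panel, function(p) {
      mx <- p$max_area_px
      if (is.null(mx) || identical(mx, "unlimited")) mx <- Inf
      marker_config(p$name, p$blue_threshold,
                    p$min_area_px %||% 1L, mx, p$mode %||% "count")
    })
    names(args$panel) <- vapply(args$panel, `[[`, character(1), "name")
  }
  if (!is.null(y$cohort)) {
    ca <- list()
    if (!is.null(y$cohort$n_per_group))
      ca$n_per_group <- unlist(y$cohort$n_per_group)
    if (!is.null(y$cohort$calcification_prob))
      ca$calcification_prob <- unlist(y$cohort$calcification_prob)
    args$cohort <- do.call(cohort_spec, ca)
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes the stages in order and writes one artifact set under
#' `config$out_dir`:
#' \enumerate{
#'   \item \emph{simulate}: cohort table (`cohort.csv`).
#'   \item \emph{quantify}: renders `n_phantoms` slide phantoms, quantifies
#'     them with the configured panel and writes measured-vs-truth rows
#'     (`phantom_quant.csv`).
#'   \item \emph{classify}: A/B/C labels for every cohort sample
#'     (`classified.csv`) plus accuracy against the generator truth on the
#'     tuber groups.
#'   \item \emph{cluster}: Ward clustering of the tuber samples on the
#'     configured features (`cluster_labels.csv`, `linkage.csv`,
#'     `dendrogram.png`) and per-feature ANOVA (`cluster_anova.csv`).
#'   \item \emph{stats}: Kruskal-Wallis per feature across the five
#'     groups, chi-square of FCD-like imaging features against tuber type,
#'     Kendall correlation of gliosis with age, and a BCa interval for the
#'     median pS6 fraction (`stats.json`).
#' }
#' A `manifest.json` lists every artifact with its MD5 checksum, the seed
#' and the package version; rerunning with the same config and seed
#' reproduces all non-image outputs bitwise.
#'
#' @param config a \code{\link{run_config}}.
#' @return the run report (also written as `manifest.json`), invisibly:
#'   list with `seed`, `stages`, `artifacts`, `classification_accuracy`,
#'   `cluster_k`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  cohort <- stage("simulate",
                  sample_cohort(config$cohort, seed = config$seed))
  empty <- is.null(cohort) || nrow(cohort) == 0L
  if (!empty)
    artifacts["cohort"] <- write_stage_csv(cohort, config$out_dir,
                                           "cohort.csv")

  # --- quantify (phantom slides) ---------------------------------------
  if (config$n_phantoms > 0L) {
    pq <- stage("quantify", {
      rows <- lapply(seq_len(config$n_phantoms), function(i) {
        ps <- phantom_spec(config$phantom_px, config$phantom_px,
                           objects = list(list(marker = "NeuN",
                                               n_objects = 6L,
                                               area_px_range = c(150L, 400L),
                                               chromogen_darkness = 60L)),
                           diffuse_positive_fraction = 0.2,
                           diffuse_mean_od = 0.3, n_nuclei = 10L)
        ph <- render_slide_phantom(ps, seed = config$seed + i)
        tissue <- segment_tissue(ph$image, ps$resolution_um_per_px)
        cnt <- count_objects(ph$image, config$panel[["NeuN"]], tissue)
        pos <- positive_pixel_mask(ph$image,
                                   config$panel[["MBP"]]$blue_threshold,
                                   tissue)
        data.frame(phantom = i,
                   neun_count = cnt$count,
                   neun_count_truth = ph$truth$object_count[["NeuN"]],
                   mbp_pct = area_fraction(pos, tissue),
                   mbp_pct_truth = ph$truth$area_fraction[["MBP"]])
      })
      do.call(rbind, rows)
    })
    artifacts["phantom_quant"] <- write_stage_csv(pq, config$out_dir,
                                                  "phantom_quant.csv")
  }

  # --- classify ---------------------------------------------------------
  accuracy <- NA_real_
  if (!empty) {
    classified <- stage("classify",
                        classify_table(cohort, config$gc_cutoff,
                                       config$dn_cutoff))
    artifacts["classified"] <- write_stage_csv(classified, config$out_dir,
                                               "classified.csv")
    tub <- classified$true_group %in% c("A", "B", "C")
    if (any(tub))
      accuracy <- mean(classified$tuber_type[tub] ==
                         classified$true_group[tub])
  }

  # --- cluster ----------------------------------------------------------
  cluster_k <- NA_integer_
  if (!empty && sum(cohort$true_group %in% c("A", "B", "C")) >=
        max(3L, config$k %||% 3L)) {
    cl <- stage("cluster", {
      tubers <- cohort[cohort$true_group %in% c("A", "B", "C"), ]
      skew <- intersect(config$cohort$skewed_features,
                        config$cluster_features)
      tr <- log_skew_transform(tubers, skew, config$epsilon)
      ward_cluster(tr, config$cluster_features, k = config$k)
    })
    cluster_k <- cl$k
    tubers <- cohort[cohort$true_group %in% c("A", "B", "C"), ]
    artifacts["cluster_labels"] <- write_stage_csv(
      data.frame(sample_id = tubers$sample_id, cluster = cl$labels),
      config$out_dir, "cluster_labels.csv")
    artifacts["linkage"] <- write_stage_csv(
      data.frame(merge_left = cl$tree$merge[, 1],
                 merge_right = cl$tree$merge[, 2],
                 height = cl$tree$height),
      config$out_dir, "linkage.csv")
    dendro <- file.path(config$out_dir, "dendrogram.png")
    png(dendro, width = 800, height = 500)
    plot(cl$tree, labels = tubers$sample_id,
         main = "Ward clustering of tuber samples", xlab = "", sub = "")
    dev.off()
    artifacts["dendrogram"] <- dendro
    anova_tab <- stage("cluster",
                       anova_feature_discrimination(
                         cohort[cohort$true_group %in% c("A", "B", "C"),
                                config$cluster_features],
                         cl$labels))
    artifacts["cluster_anova"] <- write_stage_csv(anova_tab,
                                                  config$out_dir,
                                                  "cluster_anova.csv")
  }

  # --- stats ------------------------------------------------------------
  if (!empty && length(unique(cohort$true_group)) >= 2L) {
    stats_report <- stage("stats", {
      feats <- intersect(names(default_feature_params()), names(cohort))
      kw <- lapply(feats, function(f) {
        gr <- split(cohort[[f]], cohort$true_group)
        gr <- gr[vapply(gr, length, integer(1)) > 0L]
        if (length(gr) < 2L) return(NULL)
        res <- kruskal_wallis(gr)
        list(feature = f, H = res$statistic, df = res$df,
             p = round(res$p, 3), p_raw = res$p)
      })
      out <- list(kruskal_wallis = Filter(Negate(is.null), kw))
      types <- classify_table(cohort, config$gc_cutoff,
                              config$dn_cutoff)
      tub <- types[types$true_group %in% c("A", "B", "C"), ]
      tab <- table(tub$fcd_like, tub$tuber_type)
      if (all(dim(tab) >= 2) && !any(rowSums(tab) == 0) &&
            !any(colSums(tab) == 0)) {
        cs <- chi_square(tab)
        out$chi_square_fcd_type <- list(statistic = cs$statistic,
                                        df = cs$df, p = round(cs$p, 3),
                                        p_raw = cs$p)
      }
      if (nrow(cohort) >= 3L) {
        kt <- kendall_tau(cohort$gfap_pct, cohort$age_at_surgery_y)
        out$kendall_gfap_age <- list(tau = kt$statistic,
                                     p = round(kt$p, 3), p_raw = kt$p)
      }
      if (nrow(cohort) >= 8L) {
        ci <- bca_bootstrap(cohort$ps6_pct, stats::median,
                            B = config$bootstrap_B,
                            level = config$bootstrap_level,
                            seed = config$seed)
        out$bca_median_ps6 <- list(estimate = ci$statistic,
                                   low = ci$ci[1], high = ci$ci[2],
                                   level = config$bootstrap_level)
      }
      out
    })
    stats_path <- file.path(config$out_dir, "stats.json")
    jsonlite::write_json(stats_report, stats_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    artifacts["stats"] <- stats_path
  }

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tuberquant")),
    stages = c("simulate", if (config$n_phantoms > 0L) "quantify",
               if (!empty) "classify",
               if (!is.na(cluster_k)) "cluster",
               if ("stats" %in% names(artifacts)) "stats"),
    classification_accuracy = accuracy,
    cluster_k = cluster_k,
    artifacts = lapply(artifacts, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
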