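# Configuration, provenance and end-to-end orchestration:
# simulate -> fit -> group statistics (-> figures), fully reproducible from
# (config, seed).

pipeline_defaults <- function() {
  list(
    experiment = "fmri-main", # fmri-main | fmri-control | psycho
    seed = 1L,
    out_dir = "chromsupp-out",
    conditions = chroma_levels(),
    n_subjects = NULL, # default 13 (fMRI) / 10 (psycho)
    area = "V1",
    noise_sd = 0.3, # BOLD per-block noise, percent signal change
    lapse = 0, # 2AFC observer lapse rate
    fit_n_starts = 5L, # joint-HRF outer starts
    fit_maxit = 400L,
    normalize_mode = "subtract",
    make_plots = FALSE,
    verbose = TRUE
  )
}

#' Build or load a pipeline configuration
#'
#' `pipeline_config()` fills documented defaults; `load_config()` reads a
#' YAML file, rejects unknown keys (naming them), validates values and
#' records the file's content hash as provenance. `save_config()` writes a
#' config back to YAML; a write/read round trip preserves all fields.
#'
#' @param ... Named settings overriding the defaults (see
#'   `pipeline_defaults` in the source for the full list: `experiment`,
#'   `seed`, `out_dir`, `conditions`, `n_subjects`, `area`, `noise_sd`,
#'   `lapse`, `fit_n_starts`, `fit_maxit`, `normalize_mode`, `make_plots`,
#'   `verbose`).
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(experiment = "psycho", seed = 7, n_subjects = 4)
pipeline_config <- function(...) {
  override <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg <- utils::modifyList(defaults, override)
  if (!cfg$experiment %in% c("fmri-main", "fmri-control", "psycho")) {
    stop("config key 'experiment' must be fmri-main, fmri-control or psycho",
      call. = FALSE
    )
  }
  tryCatch(check_chroma(cfg$conditions), error = function(e) {
    stop("config key 'conditions': ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(cfg$n_subjects)) {
    cfg$n_subjects <- if (cfg$experiment == "psycho") 10L else 13L
  }
  for (k in c("seed", "n_subjects", "fit_n_starts", "fit_maxit")) {
    cfg[[k]] <- as.integer(cfg[[k]])
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L) {
      stop("config key '", k, "' must be a positive integer", call. = FALSE)
    }
  }
  if (!cfg$normalize_mode %in% c("subtract", "ratio")) {
    stop("config key 'normalize_mode' must be subtract or ratio", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  cfg <- do.call(pipeline_config, raw)
  attr(cfg, "source_hash") <- fnv1a_hex(readLines(path, warn = FALSE))
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline config:", x$experiment, "| seed", x$seed,
    "|", x$n_subjects, "subjects\n"
  )
  invisible(x)
}

config_hash <- function(config) {
  attr(config, "source_hash") %||%
    fnv1a_hex(yaml::as.yaml(unclass(config)))
}

msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> group statistics for one experiment kind and
#' writes all outputs (CSV tables, a provenance stamp, optional figures)
#' under `config$out_dir`. Reruns with an identical config produce
#' byte-identical files; every stochastic stage is seeded from the config's
#' master seed. Stage failures abort with the stage name; outputs written
#' before the failure are preserved.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: output `paths`, the group
#'   `anova` and `tukey` tables, the per-subject measures table and the
#'   config.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   experiment = "psycho", n_subjects = 4,
#'   out_dir = tempfile("chromsupp")
#' )
#' res <- run_pipeline(cfg)
#' res$anova
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  paths <- list()
  write_stamp <- function() {
    stamp <- list(
      package = "chromsupp",
      version = as.character(utils::packageVersion("chromsupp")),
      seed = config$seed, config = unclass(config),
      config_hash = config_hash(config)
    )
    p <- file.path(config$out_dir, "provenance.yaml")
    yaml::write_yaml(stamp, p)
    p
  }
  paths$provenance <- write_stamp()

  if (config$experiment %in% c("fmri-main", "fmri-control")) {
    res <- run_fmri_pipeline(config, stage)
  } else {
    res <- run_psycho_pipeline(config, stage)
  }
  res$paths <- c(paths, res$paths)
  res$config <- config
  class(res) <- "pipeline_result"
  if (isTRUE(config$make_plots)) {
    res$paths$figures <- stage("figures", pipeline_figures(res, config))
  }
  res
}

run_fmri_pipeline <- function(config, stage) {
  experiment <- if (config$experiment == "fmri-main") "main" else "control"
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))

  msg(config, "simulating ", config$n_subjects, " subjects (", experiment, ")")
  sims <- stage("simulate", {
    truth <- paper_like_bold_truth(config$n_subjects,
      area = config$area,
      experiment = experiment, noise_sd = config$noise_sd, seed = config$seed
    )
    lapply(seq_along(subjects), function(s) {
      sch <- schedule_fmri(seed = derive_seed(config$seed, 61L, s))
      simulate_bold(truth[[s]], sch, subject = s)
    })
  })
  names(sims) <- subjects
  tc_path <- file.path(config$out_dir, "timecourses.csv")
  write_timecourses(sims, tc_path, area = config$area)

  msg(config, "fitting joint HRF model")
  fit_cfg <- hrf_fit_config(
    n_starts = config$fit_n_starts,
    maxit = config$fit_maxit, seed = config$seed
  )
  fits <- stage("fit", lapply(sims, fit_joint_hrf, config = fit_cfg))
  fits_df <- do.call(rbind, lapply(subjects, function(subj) {
    joint_fit_row(fits[[subj]], subj, config$area)
  }))
  fits_path <- file.path(config$out_dir, "fits.csv")
  utils::write.csv(fits_df, fits_path, row.names = FALSE)

  peaks <- do.call(rbind, lapply(subjects, function(subj) {
    pk <- fits[[subj]]$peaks
    data.frame(
      subject = subj, condition = names(pk), peak = as.numeric(pk),
      normalized = as.numeric(normalize_peaks(pk, config$normalize_mode)),
      stringsAsFactors = FALSE
    )
  }))
  peaks_path <- file.path(config$out_dir, "peaks.csv")
  utils::write.csv(peaks, peaks_path, row.names = FALSE)

  msg(config, "group statistics")
  tab <- data.frame(
    subject = peaks$subject, condition = peaks$condition,
    value = peaks$peak
  )
  anova <- stage("stats", rm_anova_oneway(tab))
  tukey <- tukey_hsd(tab, anova)
  anova_path <- file.path(config$out_dir, "anova.csv")
  utils::write.csv(as.data.frame(anova), anova_path, row.names = FALSE)
  tukey_path <- file.path(config$out_dir, "tukey.csv")
  utils::write.csv(tukey, tukey_path, row.names = FALSE)

  list(
    paths = list(
      timecourses = tc_path, fits = fits_path, peaks = peaks_path,
      anova = anova_path, tukey = tukey_path
    ),
    measures = peaks, anova = anova, tukey = tukey, fits = fits
  )
}

run_psycho_pipeline <- function(config, stage) {
  msg(config, "simulating 2AFC observers")
  trials <- stage("simulate", {
    obs <- paper_like_observer_config(config$n_subjects, seed = config$seed)
    obs$lapse <- config$lapse
    simulate_2afc(obs)
  })
  trials_path <- file.path(config$out_dir, "trials.csv")
  write_trials(trials, trials_path)

  msg(config, "fitting psychometric functions")
  rates <- aggregate_rates(trials)
  cells <- unique(rates[c("subject", "chroma")])
  sigmas <- stage("fit", do.call(rbind, lapply(
    seq_len(nrow(cells)),
    function(i) {
      cell <- rates[rates$subject == cells$subject[i] &
        rates$chroma == cells$chroma[i], ]
      fit <- fit_psychometric(cell)
      data.frame(
        subject = cells$subject[i], chroma = cells$chroma[i],
        mu = fit$mu, sigma = fit$sigma, sensitivity = fit$sensitivity,
        method = fit$method, n_trials = fit$n_trials,
        boundary = fit$boundary, stringsAsFactors = FALSE
      )
    }
  )))
  sigmas_path <- file.path(config$out_dir, "sigmas.csv")
  utils::write.csv(sigmas, sigmas_path, row.names = FALSE)

  exclusion <- exclude_subjects(sigmas)
  excl_path <- file.path(config$out_dir, "exclusion.csv")
  utils::write.csv(exclusion, excl_path, row.names = FALSE)
  retained <- exclusion$subject[!exclusion$excluded]

  msg(config, "group statistics (", length(retained), " retained subjects)")
  tab <- data.frame(
    subject = sigmas$subject, condition = sigmas$chroma,
    value = sigmas$sigma
  )
  tab <- tab[tab$subject %in% retained, ]
  anova <- stage("stats", rm_anova_oneway(tab))
  tukey <- tukey_hsd(tab, anova)
  anova_path <- file.path(config$out_dir, "anova.csv")
  utils::write.csv(as.data.frame(anova), anova_path, row.names = FALSE)
  tukey_path <- file.path(config$out_dir, "tukey.csv")
  utils::write.csv(tukey, tukey_path, row.names = FALSE)

  list(
    paths = list(
      trials = trials_path, sigmas = sigmas_path, exclusion = excl_path,
      anova = anova_path, tukey = tukey_path
    ),
    measures = sigmas, anova = anova, tukey = tukey, exclusion = exclusion
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (", x$config$experiment, ")\n", sep = "")
  cat("outputs:\n")
  for (p in unlist(x$paths)) cat("  ", p, "\n")
  print(x$anova)
  invisible(x)
}

# Condition-mean bar figure (normalized peaks or sigma), written only when
# make_plots is set; requires ggplot2.
pipeline_figures <- function(res, config) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures", call. = FALSE)
    return(NULL)
  }
  m <- res$measures
  if (config$experiment == "psycho") {
    df <- stats::aggregate(sigma ~ chroma, m, mean)
    df$sem <- stats::aggregate(sigma ~ chroma, m, function(v) {
      stats::sd(v) / sqrt(length(v))
    })$sigma
    names(df)[2] <- "value"
    ylab <- "mean psychometric sigma (contrast units)"
  } else {
    df <- stats::aggregate(normalized ~ condition, m, mean)
    df$sem <- stats::aggregate(normalized ~ condition, m, function(v) {
      stats::sd(v) / sqrt(length(v))
    })$normalized
    names(df) <- c("chroma", "value", "sem")
    ylab <- "normalized peak response (% signal change)"
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = chroma, y = value)) +
    ggplot2::geom_col(fill = "grey70", color = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = value - sem, ymax = value + sem),
      width = 0.2
    ) +
    ggplot2::labs(x = "chroma condition", y = ylab) +
    ggplot2::theme_classic()
  path <- file.path(config$out_dir, "condition_means.pdf")
  ggplot2::ggsave(path, gg, width = 4, height = 3)
  path
}
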