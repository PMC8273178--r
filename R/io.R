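# Plain-CSV interchange schemas. Real data enter the pipeline through the
# same tables the simulators emit: block-averaged time courses
# (subject, area, condition, t_s, psc, n_blocks) and 2AFC trials
# (subject, session, chroma, test_contrast, order, response).

#' Write / read block-averaged time courses
#'
#' Long-format CSV schema: `subject`, `area`, `condition`, `t_s`, `psc`,
#' `n_blocks`.
#'
#' @param timecourses Named list (by subject) of [bold_timecourses()], or a
#'   long data frame already in the schema.
#' @param path CSV path.
#' @param area Visual area label recorded with list input.
#' @return `write_timecourses()` the path, invisibly; `read_timecourses()` a
#'   validated data frame.
#' @export
write_timecourses <- function(timecourses, path, area = "V1") {
  df <- if (is.data.frame(timecourses)) {
    timecourses
  } else {
    do.call(rbind, lapply(names(timecourses), function(subj) {
      tc <- timecourses[[subj]]
      data.frame(
        subject = subj, area = area,
        condition = rep(colnames(tc$responses), each = length(tc$times)),
        t_s = rep(tc$times, ncol(tc$responses)),
        psc = as.numeric(tc$responses),
        n_blocks = tc$n_blocks, stringsAsFactors = FALSE
      )
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "area", "condition", "t_s", "psc", "n_blocks")
  if (!all(need %in% names(df))) {
    stop("timecourses CSV must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  check_chroma(unique(df$condition))
  df
}

#' Assemble one subject/area's [bold_timecourses()] from a long table
#'
#' @param df A data frame in the [read_timecourses()] schema.
#' @param subject,area Selection.
#' @return A [bold_timecourses()].
#' @export
timecourses_to_bold <- function(df, subject, area = "V1") {
  sel <- df[df$subject == subject & df$area == area, ]
  if (nrow(sel) == 0L) stop("no rows for subject ", subject, call. = FALSE)
  times <- sort(unique(sel$t_s))
  resp <- sapply(chroma_levels(), function(ch) {
    rows <- sel[sel$condition == ch, ]
    rows$psc[order(rows$t_s)]
  })
  bold_timecourses(resp, n_blocks = min(sel$n_blocks), times = times)
}

#' Write / read 2AFC trial tables
#'
#' CSV schema: `subject`, `session`, `chroma`, `test_contrast`, `order`,
#' `response` (plus optional `isi_ms`).
#'
#' @param trials Trial data frame ([simulate_2afc()] output or same schema).
#' @param path CSV path.
#' @return `write_trials()` the path, invisibly; `read_trials()` a validated
#'   data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "session", "chroma", "test_contrast", "response")
  if (!all(need %in% names(df))) {
    stop("trials CSV must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  check_chroma(unique(df$chroma))
  df
}

# One row per fitted (subject, area): shared temporal parameters, EV and
# per-condition parameters/peaks, flattened for the fits CSV.
joint_fit_row <- function(fit, subject, area = "V1") {
  tp <- fit$temporal
  row <- data.frame(
    subject = subject, area = area,
    T1 = tp$T1, T2 = tp$T2, alpha1 = tp$alpha1, alpha2 = tp$alpha2,
    ev = fit$ev, converged = fit$diagnostics$converged,
    stringsAsFactors = FALSE
  )
  for (ch in names(fit$per_condition)) {
    cp <- fit$per_condition[[ch]]
    tag <- sub("^/", "c", ch)
    row[[paste0("a1_", tag)]] <- cp$a1
    row[[paste0("a2_", tag)]] <- cp$a2
    row[[paste0("b_", tag)]] <- cp$b
    row[[paste0("d_", tag)]] <- cp$d
    row[[paste0("peak_", tag)]] <- fit$peaks[[ch]]
  }
  row
}
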