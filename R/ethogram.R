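#' @keywords internal
"_PACKAGE"

# Courtship bouts are closed intervals in seconds within a fixed observation
# window (300 s in the standard assay). All interval arithmetic uses an
# absolute tolerance of 1e-9 s; times are stored as doubles at millisecond
# resolution or better.

.TIME_TOL <- 1e-9
.CONDITIONS <- c("naive", "trained")

#' Coerce bout input to a two-column start/end matrix
#'
#' Accepts a numeric matrix, a data frame with `start`/`end` columns, or a
#' length-2 numeric vector (a single bout). A zero-row input is allowed and
#' denotes a male observed with no courtship.
#' @noRd
as_bout_matrix <- function(bouts) {
  if (is.null(bouts)) {
    b <- matrix(numeric(0), ncol = 2)
  } else if (is.data.frame(bouts)) {
    if (!all(c("start", "end") %in% names(bouts))) {
      stop("bout data frame must have 'start' and 'end' columns", call. = FALSE)
    }
    b <- cbind(as.numeric(bouts$start), as.numeric(bouts$end))
  } else if (is.matrix(bouts)) {
    if (ncol(bouts) != 2) stop("bout matrix must have two columns", call. = FALSE)
    b <- matrix(as.numeric(bouts), ncol = 2)
  } else if (is.numeric(bouts) && length(bouts) == 2) {
    b <- matrix(bouts, ncol = 2)
  } else if (is.numeric(bouts) && length(bouts) == 0) {
    b <- matrix(numeric(0), ncol = 2)
  } else {
    stop("cannot interpret 'bouts' as start/end intervals", call. = FALSE)
  }
  colnames(b) <- c("start", "end")
  b
}

#' Normalize a set of courtship bouts
#'
#' Validates, clips, sorts and merges the bout intervals of one male so that
#' the result is a set of pairwise non-overlapping intervals inside
#' `[0, window]`. Overlapping bouts are merged (interval union), never
#' summed, so total courtship time cannot exceed the window. Bouts extending
#' past the window are clipped with a warning; bouts lying entirely outside
#' it are dropped with a warning.
#'
#' @param bouts A two-column numeric matrix (or data frame with `start`,
#'   `end`) of bout start/end times in seconds; zero rows allowed.
#' @param window Observation window length in seconds (default 300, the
#'   standard courtship-assay period).
#' @param context Optional label (e.g. a male id) used in error messages.
#' @return A two-column matrix (`start`, `end`) of disjoint, sorted,
#'   clipped intervals. Total covered time is invariant under the input
#'   ordering of bouts.
#' @examples
#' normalize_bouts(rbind(c(0, 10), c(5, 20)))
#' @export
normalize_bouts <- function(bouts, window = 300, context = NULL) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window <= 0) {
    stop("'window' must be a single positive number of seconds", call. = FALSE)
  }
  b <- as_bout_matrix(bouts)
  if (nrow(b) == 0L) return(b)
  who <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (any(!is.finite(b))) {
    stop("non-finite bout times", who, call. = FALSE)
  }
  if (any(b[, 1L] < 0)) {
    stop("negative bout start time", who, call. = FALSE)
  }
  bad <- which(b[, 2L] <= b[, 1L])
  if (length(bad)) {
    stop(sprintf("bout with end <= start (row %d)%s", bad[1L], who),
         call. = FALSE)
  }
  outside <- b[, 1L] >= window
  if (any(outside)) {
    warning(sprintf("%d bout(s) entirely outside the %g-s window dropped%s",
                    sum(outside), window, who), call. = FALSE)
    b <- b[!outside, , drop = FALSE]
    if (nrow(b) == 0L) return(b)
  }
  if (any(b[, 2L] > window)) {
    warning(sprintf("%d bout(s) clipped to the %g-s window%s",
                    sum(b[, 2L] > window), window, who), call. = FALSE)
    b[, 2L] <- pmin(b[, 2L], window)
  }
  b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
  # sweep-merge the union of intervals
  ms <- me <- numeric(nrow(b))
  k <- 1L
  ms[1L] <- b[1L, 1L]
  me[1L] <- b[1L, 2L]
  if (nrow(b) > 1L) {
    for (i in 2L:nrow(b)) {
      if (b[i, 1L] <= me[k] + .TIME_TOL) {
        me[k] <- max(me[k], b[i, 2L])
      } else {
        k <- k + 1L
        ms[k] <- b[i, 1L]
        me[k] <- b[i, 2L]
      }
    }
  }
  out <- cbind(start = ms[seq_len(k)], end = me[seq_len(k)])
  out
}

#' Courtship index of one male
#'
#' The courtship index (CI) is the percentage of the observation window the
#' male spent courting: `CI = 100 * total bout time / window`. Bouts are
#' normalized first (union of intervals, clipped to the window), so
#' `0 <= CI <= 100` always. A male observed with no bouts has CI 0.
#'
#' @inheritParams normalize_bouts
#' @return CI as a percentage in `[0, 100]`.
#' @examples
#' compute_ci(rbind(c(0, 100), c(50, 200)))  # union is 200 s -> 66.67
#' @export
compute_ci <- function(bouts, window = 300, context = NULL) {
  nb <- normalize_bouts(bouts, window = window, context = context)
  if (nrow(nb) == 0L) return(0)
  100 * sum(nb[, 2L] - nb[, 1L]) / window
}

.ETHOGRAM_HEADER <- c("male_id", "strain", "condition", "timepoint",
                      "timepoint_unit", "window_s", "bout_start_s",
                      "bout_end_s")

#' Read a courtship ethogram CSV
#'
#' One row per scored bout; a male observed with no courtship appears as a
#' single row with empty `bout_start_s`/`bout_end_s` fields (his CI is 0 —
#' distinct from a male absent from the file). Rows are grouped by
#' `male_id`, bouts are normalized (merged/clipped) per male, and the CI is
#' computed. A summary of row counts and placeholder rows is emitted as a
#' message.
#'
#' @param path Path to a UTF-8 comma-separated file with header
#'   `male_id,strain,condition,timepoint,timepoint_unit,window_s,bout_start_s,bout_end_s`.
#' @return A tibble with one row per male: `male_id`, `strain`, `condition`
#'   (`"naive"` or `"trained"`), `timepoint` (character label),
#'   `timepoint_unit` (`"minutes"` or `"days"`), `window`, `bouts` (list
#'   column of normalized start/end matrices) and `ci`.
#' @export
read_ethograms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, .ETHOGRAM_HEADER)) {
    stop("malformed ethogram header at line 1: expected ",
         paste(.ETHOGRAM_HEADER, collapse = ","), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(male_id = "character",
                                       strain = "character",
                                       condition = "character",
                                       timepoint = "character",
                                       timepoint_unit = "character"))
  line <- seq_len(nrow(df)) + 1L  # file line numbers (header is line 1)
  bad_cond <- !(df$condition %in% .CONDITIONS)
  if (any(bad_cond)) {
    stop(sprintf("unknown condition '%s' at line %d",
                 df$condition[bad_cond][1L], line[bad_cond][1L]),
         call. = FALSE)
  }
  if (any(!(df$timepoint_unit %in% c("minutes", "days")))) {
    i <- which(!(df$timepoint_unit %in% c("minutes", "days")))[1L]
    stop(sprintf("unknown timepoint_unit '%s' at line %d",
                 df$timepoint_unit[i], line[i]), call. = FALSE)
  }
  if (any(!is.finite(df$window_s) | df$window_s <= 0)) {
    i <- which(!is.finite(df$window_s) | df$window_s <= 0)[1L]
    stop(sprintf("invalid window_s at line %d", line[i]), call. = FALSE)
  }
  half <- xor(is.na(df$bout_start_s), is.na(df$bout_end_s))
  if (any(half)) {
    stop(sprintf("bout with only one endpoint at line %d",
                 line[half][1L]), call. = FALSE)
  }
  has_bout <- !is.na(df$bout_start_s)
  neg <- has_bout & (df$bout_start_s < 0 | df$bout_end_s < 0)
  if (any(neg)) {
    stop(sprintf("negative bout time at line %d", line[neg][1L]),
         call. = FALSE)
  }
  rev_b <- has_bout & df$bout_end_s <= df$bout_start_s
  if (any(rev_b)) {
    i <- which(rev_b)[1L]
    stop(sprintf("bout end <= start for male '%s' at line %d",
                 df$male_id[i], line[i]), call. = FALSE)
  }

  males <- split(df, factor(df$male_id, levels = unique(df$male_id)))
  obs <- lapply(males, function(d) {
    for (col in c("strain", "condition", "timepoint", "timepoint_unit",
                  "window_s")) {
      if (length(unique(d[[col]])) != 1L) {
        stop(sprintf("male '%s' has inconsistent '%s' across rows",
                     d$male_id[1L], col), call. = FALSE)
      }
    }
    keep <- !is.na(d$bout_start_s)
    b <- cbind(start = d$bout_start_s[keep], end = d$bout_end_s[keep])
    nb <- normalize_bouts(b, window = d$window_s[1L],
                          context = paste0("male ", d$male_id[1L]))
    tibble::tibble(male_id = d$male_id[1L], strain = d$strain[1L],
                   condition = d$condition[1L], timepoint = d$timepoint[1L],
                   timepoint_unit = d$timepoint_unit[1L],
                   window = d$window_s[1L], bouts = list(nb),
                   ci = compute_ci(nb, d$window_s[1L]))
  })
  out <- do.call(rbind, c(obs, list(make.row.names = FALSE)))
  out <- tibble::as_tibble(out)
  message(sprintf("read %d row(s): %d male(s), %d bout row(s), %d zero-courtship placeholder row(s)",
                  nrow(df), nrow(out), sum(has_bout), sum(!has_bout)))
  out
}

#' Write observations back to the ethogram CSV dialect
#'
#' Inverse of [read_ethograms()]: one row per bout, one placeholder row with
#' empty bout fields for a male with no courtship. Times are written with
#' full double precision so a read/write round trip preserves CIs exactly.
#'
#' @param observations Tibble as returned by [read_ethograms()] or
#'   [generate_ethograms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ethograms <- function(observations, path) {
  fmt <- function(x) sprintf("%.17g", x)
  rows <- lapply(seq_len(nrow(observations)), function(i) {
    o <- observations[i, ]
    b <- o$bouts[[1L]]
    n <- max(1L, nrow(b))
    data.frame(male_id = rep(o$male_id, n), strain = rep(o$strain, n),
               condition = rep(o$condition, n),
               timepoint = rep(o$timepoint, n),
               timepoint_unit = rep(o$timepoint_unit, n),
               window_s = rep(fmt(o$window), n),
               bout_start_s = if (nrow(b)) fmt(b[, 1L]) else "",
               bout_end_s = if (nrow(b)) fmt(b[, 2L]) else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate per-male courtship indices into group samples
#'
#' Builds one group per (strain, condition, timepoint): the labelled CI
#' samples that feed the learning-index and randomization machinery. Naive
#' and trained samples of the same strain/timepoint are independent cohorts
#' of different males.
#'
#' @param observations Tibble of per-male observations with at least
#'   `male_id`, `strain`, `condition`, `timepoint`, `timepoint_unit`, `ci`.
#' @return A tibble with columns `strain`, `condition`, `timepoint`,
#'   `timepoint_unit`, `n` and `cis` (list column of CI vectors).
#' @export
aggregate_groups <- function(observations) {
  if (nrow(observations) == 0L) {
    return(tibble::tibble(strain = character(), condition = character(),
                          timepoint = character(),
                          timepoint_unit = character(),
                          n = integer(), cis = list()))
  }
  key <- paste(observations$strain, observations$condition,
               observations$timepoint, sep = "\r")
  pieces <- split(observations, factor(key, levels = unique(key)))
  rows <- lapply(pieces, function(d) {
    dup <- d$male_id[duplicated(d$male_id)]
    if (length(dup)) {
      stop(sprintf("duplicate male_id '%s' within group %s/%s/%s (independence violated)",
                   dup[1L], d$strain[1L], d$condition[1L], d$timepoint[1L]),
           call. = FALSE)
    }
    tibble::tibble(strain = d$strain[1L], condition = d$condition[1L],
                   timepoint = d$timepoint[1L],
                   timepoint_unit = d$timepoint_unit[1L],
                   n = nrow(d), cis = list(d$ci))
  })
  out <- tibble::as_tibble(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  tp_num <- suppressWarnings(as.numeric(out$timepoint))
  ord <- order(out$strain, tp_num, out$timepoint, out$condition)
  out[ord, ]
}
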