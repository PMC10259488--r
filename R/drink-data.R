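#' Minute-resolution drinking log for one mouse
#'
#' A `drink_log` holds the cumulative volume drunk from each of the two
#' bottles of a continuous-access two-bottle choice cage, sampled at minute
#' resolution by the acquisition system. Volumes are cumulative from the
#' start of the experiment, so gaps in the minute series are harmless: a
#' missing minute simply means no drinking was recorded then.
#'
#' @param mouse_id Single string identifying the animal.
#' @param minute Integer-valued vector of minutes since experiment start,
#'   strictly increasing. Minute 0 is the first minute of day 1.
#' @param volume_left,volume_right Cumulative volumes (ml) for the left and
#'   right bottle at each minute; non-negative and non-decreasing.
#' @return An object of class `drink_log`: a data frame with columns
#'   `minute`, `volume_left`, `volume_right` and attribute `mouse_id`.
#' @export
drink_log <- function(mouse_id, minute, volume_left, volume_right) {
  stopifnot(is.character(mouse_id), length(mouse_id) == 1L)
  minute <- as.numeric(minute)
  volume_left <- as.numeric(volume_left)
  volume_right <- as.numeric(volume_right)
  n <- length(minute)
  if (length(volume_left) != n || length(volume_right) != n)
    stop("volume series must have the same length as the minute series")
  if (n == 0L) stop("empty drinking log for mouse ", mouse_id)
  if (anyDuplicated(minute))
    stop("duplicated minute in log for mouse ", mouse_id, ": minute ",
         minute[anyDuplicated(minute)])
  if (is.unsorted(minute, strictly = TRUE))
    stop("timestamps not strictly increasing for mouse ", mouse_id)
  for (side in c("left", "right")) {
    v <- if (side == "left") volume_left else volume_right
    if (any(v < 0))
      stop("negative cumulative volume for mouse ", mouse_id)
    bad <- which(diff(v) < 0)
    if (length(bad))
      stop("cumulative volume decreased for mouse ", mouse_id,
           " (", side, " bottle) at minute ", minute[bad[1L] + 1L])
  }
  out <- data.frame(minute = minute, volume_left = volume_left,
                    volume_right = volume_right)
  attr(out, "mouse_id") <- mouse_id
  class(out) <- c("drink_log", "data.frame")
  out
}

#' @export
print.drink_log <- function(x, ...) {
  cat("<drink_log> mouse", attr(x, "mouse_id"), "-", nrow(x),
      "observations spanning minutes", x$minute[1L], "to",
      x$minute[nrow(x)], "\n")
  invisible(x)
}

#' Read drinking logs from a delimited text file
#'
#' Expects a header with columns `mouse_id`, `minute`, `volume_left_ml`,
#' `volume_right_ml` (cumulative ml). Delimiter is inferred from the file
#' extension: `.tsv`/`.txt` are tab-separated, anything else comma. Rows
#' may arrive unsorted; they are sorted by minute per mouse. Missing
#' minutes are accepted, duplicated minutes and non-monotone cumulative
#' volumes are hard errors.
#'
#' @param path Path to the log file.
#' @return Named list of [drink_log] objects, one per mouse.
#' @export
read_drink_log <- function(path) {
  tab <- read_table_auto(path)
  need <- c("mouse_id", "minute", "volume_left_ml", "volume_right_ml")
  if (!all(need %in% names(tab)))
    stop("drink log file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$mouse_id), function(d) {
    d <- d[order(d$minute), , drop = FALSE]
    drink_log(as.character(d$mouse_id[1L]), d$minute,
              d$volume_left_ml, d$volume_right_ml)
  })
  out[order(names(out))]
}

#' Write drinking logs to a delimited text file
#'
#' Inverse of [read_drink_log()]; volumes are written with 3 decimals (the
#' acquisition precision), so a read/write round trip is lossless at that
#' precision.
#'
#' @param logs A `drink_log` or list of them.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_drink_log <- function(logs, path) {
  if (inherits(logs, "drink_log")) logs <- list(logs)
  tab <- do.call(rbind, lapply(logs, function(l) {
    data.frame(mouse_id = attr(l, "mouse_id"), minute = l$minute,
               volume_left_ml = sprintf("%.3f", l$volume_left),
               volume_right_ml = sprintf("%.3f", l$volume_right))
  }))
  write_table_auto(tab, path)
  invisible(path)
}

#' Per-mouse record: body weights and tags
#'
#' Mice are weighed only every other day, so weights are sparse by day.
#' [weight_on_day()] fills the gaps by step carry-forward (and
#' carry-backward before the first record).
#'
#' @param mouse_id Single string.
#' @param weights Named numeric vector, names = 1-based day indices,
#'   values = grams. At least one entry; all positive.
#' @param tags Character vector of free-form group labels (genotype,
#'   treatment, ...).
#' @return Object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, weights, tags = character()) {
  stopifnot(is.character(mouse_id), length(mouse_id) == 1L)
  w <- as.numeric(weights)
  d <- as.integer(names(weights))
  if (length(w) == 0L || any(is.na(d)))
    stop("weights must be a named vector with day-index names")
  if (any(w <= 0)) stop("non-positive body weight for mouse ", mouse_id)
  o <- order(d)
  structure(list(mouse_id = mouse_id, weight_days = d[o], weights = w[o],
                 tags = tags),
            class = "mouse_record")
}

#' Body weight on a given day (step interpolation)
#'
#' Returns the recorded weight for `day` if present, otherwise the nearest
#' earlier recorded weight (carry-forward); before the first record, the
#' first recorded weight (carry-backward).
#'
#' @param rec A [mouse_record].
#' @param day 1-based day index (vectorised).
#' @return Weight(s) in grams.
#' @export
weight_on_day <- function(rec, day) {
  idx <- findInterval(day, rec$weight_days)
  idx[idx < 1L] <- 1L
  rec$weights[idx]
}

#' Read a per-mouse weight table
#'
#' Columns: `mouse_id`, `day`, `weight_g` (grams, 1 decimal). Optional
#' extra columns are collected as tags columns and attached verbatim.
#'
#' @param path Path to a CSV/TSV weight table.
#' @param tags Optional data frame with columns `mouse_id` plus tag
#'   columns; alternatively a `tag` column in the weight file itself.
#' @return Named list of [mouse_record] objects.
#' @export
read_weights <- function(path, tags = NULL) {
  tab <- read_table_auto(path)
  need <- c("mouse_id", "day", "weight_g")
  if (!all(need %in% names(tab)))
    stop("weight file must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$mouse_id), function(d) {
    w <- d$weight_g
    names(w) <- d$day
    tg <- if ("tag" %in% names(d)) unique(as.character(d$tag)) else character()
    if (!is.null(tags)) {
      row <- tags[tags$mouse_id == d$mouse_id[1L], , drop = FALSE]
      if (nrow(row)) tg <- c(tg, unlist(lapply(row[-1], as.character)))
    }
    mouse_record(as.character(d$mouse_id[1L]), w, tg)
  })
}

#' Write per-mouse weights
#' @param recs List of [mouse_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(recs, path) {
  if (inherits(recs, "mouse_record")) recs <- list(recs)
  tab <- do.call(rbind, lapply(recs, function(r) {
    data.frame(mouse_id = r$mouse_id, day = r$weight_days,
               weight_g = sprintf("%.1f", r$weights))
  }))
  write_table_auto(tab, path)
  invisible(path)
}

# Delimiter-by-extension read/write used for all tabular dialects.
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop("empty table: ", path)
  tab
}

write_table_auto <- function(tab, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}
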