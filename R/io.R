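#' Read tracklets from CSV
#'
#' Reads the tracklet CSV dialect: header
#' `tracklet_id,hive,comb,side,t,x,y`, comma-separated, `.` decimal,
#' UTF-8; `comb` in `{upper, lower}`, `side` in `{front, back}`; `t` in
#' seconds, `x`/`y` in cm. Optional `state` and `p_walk` columns (as
#' written by [segment_activity()]) are carried through.
#'
#' Rows are grouped by `tracklet_id` and sorted by time; back-side rows
#' are mirrored to front-side coordinates via [flip_back_side()]; all
#' positions must fall inside the accessible region.
#'
#' @param path CSV file path.
#' @param arena an [arena_geometry()] object used for validation and the
#'   back-side flip.
#' @return a tibble of tracklet samples (one row per detection) with the
#'   arena attached as attribute `"arena"`.
#' @export
read_tracklets <- function(path, arena = arena_geometry()) {
  required <- c("tracklet_id", "hive", "comb", "side", "t", "x", "y")
  df <- tryCatch(
    suppressWarnings(utils::read.csv(path, stringsAsFactors = FALSE,
                                     encoding = "UTF-8")),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("tracklet file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    attr(df, "arena") <- arena
    return(df)
  }
  bad <- which(!is.finite(df$t) | !is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1,
         " (non-numeric t/x/y)", call. = FALSE)
  }
  if (!all(df$comb %in% c("upper", "lower"))) {
    stop("comb must be 'upper' or 'lower'", call. = FALSE)
  }
  if (!all(df$side %in% c("front", "back"))) {
    stop("side must be 'front' or 'back'", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$tracklet_id, .data$t)
  if (any(df$side == "back")) df <- flip_back_side(df, arena)
  out_of <- !arena_contains(arena, df$x, df$y)
  if (any(out_of)) {
    stop("position outside accessible region in tracklet '",
         df$tracklet_id[which(out_of)[1]], "'", call. = FALSE)
  }
  nondec <- df |>
    dplyr::group_by(.data$tracklet_id) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0) || dplyr::n() == 1) |>
    dplyr::filter(!.data$ok)
  if (nrow(nondec)) {
    stop("timestamps not strictly increasing in tracklet '",
         nondec$tracklet_id[1], "'", call. = FALSE)
  }
  attr(df, "arena") <- arena
  df
}

#' Write tracklets to CSV
#'
#' @param tracklets tracklet tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracklets <- function(tracklets, path) {
  keep <- intersect(c("tracklet_id", "hive", "comb", "side", "t", "x", "y",
                      "state", "p_walk"), names(tracklets))
  utils::write.csv(as.data.frame(tracklets)[, keep], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an analysis product to schema-versioned JSON
#'
#' Writes a JSON object with a `schema_version` field, the parameters
#' used, the seed, and the payload. Re-serializing the same object yields
#' a byte-identical file; `NaN`/`NA` entries are serialized as `null`.
#'
#' @param results any serializable analysis product (tibbles are written
#'   column-wise).
#' @param path output path.
#' @param parameters named list of parameters recorded alongside.
#' @param seed seed recorded alongside (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, parameters = list(), seed = NULL) {
  payload <- results
  if (inherits(payload, "metric_curve")) {
    payload <- list(curve = tibble::as_tibble(payload),
                    fit = attr(results, "fit"))
  }
  obj <- list(schema_version = "1.0",
              parameters = parameters,
              seed = seed,
              results = payload)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  txt <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA, null = "null", na = "null",
                          pretty = TRUE)
  writeLines(txt, con)
  invisible(path)
}
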