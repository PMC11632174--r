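#' Input transforms for the competitor design space
#'
#' The design inputs enter the surrogates as `log(BP)` and `logit(GC)`,
#' which spreads the log-spaced base-pair grid and the bounded GC fraction
#' onto unbounded, roughly homogeneous scales.
#'
#' @param bp base-pair counts (>= 1).
#' @param gc GC fractions strictly inside (0, 1).
#' @return matrix with columns `u1 = log(bp)` and `u2 = logit(gc)`.
#' @export
transform_inputs <- function(bp, gc) {
  if (any(bp < 1)) stop("bp must be >= 1", call. = FALSE)
  if (any(gc <= 0 | gc >= 1)) stop("gc must lie strictly inside (0, 1)", call. = FALSE)
  cbind(u1 = log(bp), u2 = log(gc / (1 - gc)))
}

#' Invert the input transform
#'
#' @param u matrix with columns `(log bp, logit gc)`.
#' @return data.frame with `bp` and `gc`.
#' @export
inverse_transform_inputs <- function(u) {
  u <- as_matrix_input(u)
  data.frame(bp = exp(u[, 1]), gc = 1 / (1 + exp(-u[, 2])))
}

# per-output z-scoring fitted on training rows only; inverse for reporting
fit_standardizer <- function(y) {
  m <- mean(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) s <- 1
  list(mean = m, sd = s)
}
standardize <- function(y, st) (y - st$mean) / st$sd
unstandardize_mean <- function(mu, st) mu * st$sd + st$mean
unstandardize_var <- function(v, st) v * st$sd^2

#' Read a competitor observation table
#'
#' Expects a delimited text file (comma-separated, `#` comments allowed)
#' with columns `competitor_id, probe, primer_fw, primer_rv, bp, gc, rate,
#' drift` (an optional `replicate` column is preserved). Validation errors
#' name the offending rows.
#'
#' @param path file path.
#' @return object of class `competitor_data` (without truth functions).
#' @export
read_competitor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("competitor_id", "probe", "primer_fw", "primer_rv",
                "bp", "gc", "rate", "drift")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("bp", "gc", "rate", "drift")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' in rows: %s", col,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- v
  }
  bad_gc <- which(tab$gc <= 0 | tab$gc >= 1)
  if (length(bad_gc)) {
    stop("gc outside (0,1) in rows: ", paste(head(bad_gc, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_bp <- which(tab$bp < 1)
  if (length(bad_bp)) {
    stop("bp < 1 in rows: ", paste(head(bad_bp, 5), collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  metadata <- unique(tab[, c("competitor_id", "probe", "primer_fw", "primer_rv")])
  names(metadata)[1] <- "surface"
  rownames(metadata) <- NULL
  structure(list(table = tab, metadata = metadata, truth = NULL,
                 target_surfaces = NULL, anchor_surfaces = NULL,
                 spec = list(path = path)),
            class = "competitor_data")
}

#' Write a competitor observation table
#'
#' Writes the schema [read_competitor_table()] reads, with a provenance
#' comment line (seed and a configuration hash) ahead of the header.
#'
#' @param cdata a `competitor_data` object (or plain data.frame).
#' @param path output file path.
#' @param seed seed recorded in the provenance comment.
#' @return `path`, invisibly.
#' @export
write_competitor_table <- function(cdata, path, seed = NA) {
  tab <- if (inherits(cdata, "competitor_data")) cdata$table else cdata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tldoe competitor table | seed=%s | hash=%s",
                     seed, config_hash(tab)), con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces
#'
#' Delimited text with columns `well_id, cycle, fluorescence`.
#'
#' @param path file path.
#' @return data.frame of traces.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("well_id", "cycle", "fluorescence")
  missing <- setdiff(required, names(tr))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tr
}

# small deterministic content hash for provenance comments
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, give.attr = FALSE)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

# build a mo_dataset (transformed inputs) for one output of a competitor table
competitor_mo <- function(cdata, output = c("rate", "drift"), rows = NULL) {
  output <- match.arg(output)
  tab <- cdata$table
  if (!is.null(rows)) tab <- tab[rows, , drop = FALSE]
  U <- transform_inputs(tab$bp, tab$gc)
  all_labels <- unique(cdata$table$competitor_id)
  mo_dataset(U, tab[[output]], tab$competitor_id, surface_labels = all_labels)
}
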