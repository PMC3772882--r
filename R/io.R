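#' Read a delimited feature table
#'
#' One row per trial, feature columns first, the last column a class
#' label.  A header row is auto-detected: if any feature cell of the
#' first row is non-numeric, the row is treated as a header.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return list with \code{x} (numeric matrix) and \code{class_ids}
#'   (character vector); row order preserved.
#' @export
read_feature_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("feature table needs at least one row and two columns")
  feat_cols <- seq_len(ncol(raw) - 1L)
  first_numeric <- suppressWarnings(as.numeric(raw[1, feat_cols]))
  has_header <- anyNA(first_numeric)
  if (has_header) {
    header <- unlist(raw[1, feat_cols], use.names = FALSE)
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0L) stop("feature table has a header but no data rows")
  } else {
    header <- paste0("V", feat_cols)
  }
  x <- suppressWarnings(
    vapply(feat_cols, function(j) as.numeric(raw[[j]]), numeric(nrow(raw))))
  x <- matrix(x, nrow = nrow(raw), dimnames = list(NULL, header))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric feature cell at row %d, column %d",
                 bad[1], bad[2]))
  }
  list(x = x, class_ids = as.character(raw[[ncol(raw)]]))
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]: features first, label last, with a
#' header row.
#'
#' @param x numeric feature matrix.
#' @param class_ids per-row class labels.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_feature_table <- function(x, class_ids, path, sep = ",") {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(class_ids))
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(x, label = as.character(class_ids))
  names(df) <- c(cn, "label")
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

ZLDA_SCHEMA_VERSION <- 1L

#' Serialize a Z-LDA model to JSON
#'
#' Writes all model fields at full double precision, so a load/save
#' round-trip reproduces predictions bit for bit.
#'
#' @param model a fitted \code{zlda} object.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "zlda"))
  doc <- list(schema_version = ZLDA_SCHEMA_VERSION,
              bias = model$weights$bias,
              weights = model$weights$weights,
              coding = model$coding,
              classes = model$classes,
              sd_denom = model$sd_denom,
              class1 = model$dist1[c("mu", "sigma", "n")],
              class2 = model$dist2[c("mu", "sigma", "n")])
  # 17 significant digits: the shortest representation guaranteed to
  # round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a Z-LDA model from JSON
#'
#' @param path path written by [save_model()].
#' @return a \code{zlda} object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(doc$schema_version))
    stop("not a zlda model file (missing schema_version)")
  if (doc$schema_version != ZLDA_SCHEMA_VERSION)
    stop(sprintf("model schema version %s not supported (this build reads %d)",
                 doc$schema_version, ZLDA_SCHEMA_VERSION))
  w <- structure(list(bias = doc$bias, weights = as.numeric(doc$weights)),
                 class = "augmented_weights")
  structure(list(weights = w,
                 dist1 = score_distribution(doc$class1$mu, doc$class1$sigma,
                                            doc$class1$n),
                 dist2 = score_distribution(doc$class2$mu, doc$class2$sigma,
                                            doc$class2$n),
                 coding = as.numeric(doc$coding),
                 classes = as.character(doc$classes),
                 sd_denom = doc$sd_denom),
            class = "zlda")
}

#' Write multichannel trials to a directory
#'
#' One delimited file per trial (channels in rows, samples in columns)
#' plus a \code{manifest.csv} with columns \code{file}, \code{label},
#' \code{fs}.
#'
#' @param trials a [trial_array()].
#' @param dir output directory (created if needed).
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_array"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(trials$data)[1]
  files <- sprintf("trial_%04d.csv", seq_len(n))
  for (i in seq_len(n))
    utils::write.table(trials$data[i, , ], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(file = files, label = trials$labels, fs = trials$fs),
    file.path(dir, "manifest.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Read multichannel trials from a directory written by [write_trials()]
#'
#' @param dir directory with a \code{manifest.csv}.
#' @return a [trial_array()].
#' @export
read_trials <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "label", "fs") %in% names(mf)), nrow(mf) >= 1)
  mats <- lapply(mf$file, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = ",")))
  d <- dim(mats[[1]])
  data <- array(0, dim = c(nrow(mf), d[1], d[2]))
  for (i in seq_along(mats)) data[i, , ] <- mats[[i]]
  trial_array(data, mf$fs[1], mf$label)
}

# Timestamp-free metadata sidecar so identical reruns are byte-identical.
write_run_metadata <- function(out_path, command, config, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  meta <- list(command = command,
               package_version = as.character(utils::packageVersion("zlda")),
               seed = seed,
               config = config,
               config_hash = digest_string(cfg_json))
  jsonlite::write_json(meta, paste0(out_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(meta)
}

# Small FNV-1a hash (32-bit, done in exact double arithmetic); enough to
# fingerprint a config in run metadata.
digest_string <- function(s) {
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
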