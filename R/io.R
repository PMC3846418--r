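#' Read and write fingerprint datasets as dense CSV
#'
#' The dense format has a header `id,label,f1,...,fL` (the `label` column is
#' optional; without it the dataset is usable only for prediction and
#' diagnosis) and one compound per row with 0/1 cells. Column order in the
#' header defines the canonical feature order. Ragged rows, non-binary cells
#' and duplicate ids are errors reported with their line number.
#'
#' @param path File path.
#' @param levels Optional class levels fixing the label-to-index mapping.
#' @return `read_fp_csv()` returns an `fp_data`; `write_fp_csv()` returns
#'   `path` invisibly.
#' @export
read_fp_csv <- function(path, levels = NULL) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) {
      rlang::abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
        class = "lapnb_format_error"
      )
    }
  )
  if (!"id" %in% names(df)) {
    rlang::abort("dense CSV must have an 'id' column", class = "lapnb_format_error")
  }
  has_label <- "label" %in% names(df)
  feat_cols <- setdiff(names(df), c("id", "label"))
  if (length(feat_cols) == 0L) {
    rlang::abort("dense CSV has no feature columns", class = "lapnb_format_error")
  }
  if (anyDuplicated(df$id)) {
    line <- which(duplicated(df$id))[1L] + 1L # +1 for the header line
    rlang::abort(sprintf("duplicate compound id '%s' at line %d", df$id[line - 1L], line),
      class = "lapnb_format_error"
    )
  }
  x <- as.matrix(df[feat_cols])
  bad <- which(!(x %in% c("0", "1")))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(x))
    rlang::abort(
      sprintf(
        "non-binary cell '%s' at line %d, feature column '%s'",
        x[bad[1L]], rc[1L] + 1L, feat_cols[rc[2L]]
      ),
      class = "lapnb_format_error"
    )
  }
  storage.mode(x) <- "integer"
  fp_data(x,
    labels = if (has_label) df$label else NULL,
    ids = df$id, levels = levels
  )
}

#' @rdname read_fp_csv
#' @param data An `fp_data` object.
#' @export
write_fp_csv <- function(data, path) {
  stopifnot(inherits(data, "fp_data"))
  df <- as.data.frame(data$x)
  if (!is.null(data$labels)) df <- cbind(label = data$levels[data$labels], df)
  df <- cbind(id = data$ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fingerprint datasets as sparse feature lists
#'
#' A compact format for sparse fingerprints (where the typical compound has
#' few of the potentially thousands of features set). Grammar:
#'
#' ```
#' L=<integer>                      # header: total feature count
#' <id> TAB <label> TAB <j1> <j2> ...   # one compound per line
#' ```
#'
#' Feature indices are 1-based and space-separated; a compound with no
#' present features has an empty index field; the label field is `-` for
#' unlabelled compounds. Indices outside `[1, L]` or duplicated on a line
#' are errors reported with their line number.
#'
#' @inheritParams read_fp_csv
#' @return `read_fp_sparse()` returns an `fp_data`; `write_fp_sparse()`
#'   returns `path` invisibly.
#' @export
read_fp_sparse <- function(path, levels = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !grepl("^L=\\d+$", trimws(lines[1L]))) {
    rlang::abort("sparse file must start with a header line 'L=<integer>'",
      class = "lapnb_format_error"
    )
  }
  L <- as.integer(sub("^L=", "", trimws(lines[1L])))
  body <- lines[-1L]
  n <- length(body)
  x <- matrix(0L, nrow = n, ncol = L)
  ids <- character(n)
  labels <- character(n)
  for (r in seq_len(n)) {
    parts <- strsplit(body[r], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      rlang::abort(sprintf("line %d: expected 'id<TAB>label<TAB>indices'", r + 1L),
        class = "lapnb_format_error"
      )
    }
    ids[r] <- parts[1L]
    labels[r] <- parts[2L]
    idx_str <- if (length(parts) >= 3L) trimws(parts[3L]) else ""
    if (nzchar(idx_str)) {
      idx <- suppressWarnings(as.integer(strsplit(idx_str, "\\s+")[[1L]]))
      if (anyNA(idx) || any(idx < 1L) || any(idx > L)) {
        rlang::abort(sprintf("line %d: feature index outside [1, %d]", r + 1L, L),
          class = "lapnb_format_error"
        )
      }
      if (anyDuplicated(idx)) {
        rlang::abort(sprintf("line %d: duplicate feature index %d", r + 1L, idx[duplicated(idx)][1L]),
          class = "lapnb_format_error"
        )
      }
      x[r, idx] <- 1L
    }
  }
  unlabelled <- all(labels == "-")
  if (!unlabelled && any(labels == "-")) {
    rlang::abort("mixing labelled and unlabelled compounds is not supported",
      class = "lapnb_format_error"
    )
  }
  fp_data(x,
    labels = if (unlabelled) NULL else labels,
    ids = ids, levels = levels
  )
}

#' @rdname read_fp_sparse
#' @param data An `fp_data` object.
#' @export
write_fp_sparse <- function(data, path) {
  stopifnot(inherits(data, "fp_data"))
  lab <- if (is.null(data$labels)) rep("-", data$N) else data$levels[data$labels]
  body <- vapply(seq_len(data$N), function(r) {
    paste(data$ids[r], lab[r],
      paste(which(data$x[r, ] == 1L), collapse = " "),
      sep = "\t"
    )
  }, character(1))
  writeLines(c(sprintf("L=%d", data$L), body), path)
  invisible(path)
}

# doubles <-> strings that survive a round trip bit-exactly
num_out <- function(v) sprintf("%.17g", v)
num_in <- function(v) as.numeric(v)

MODEL_FORMAT_VERSION <- 1L

#' Serialize and restore a fitted model
#'
#' Models are written as versioned JSON holding the sufficient statistics,
#' hyperparameters, prior, mode, smoothing constant (for lcmnb-mode
#' models), the label-to-index map, and the log posterior tables. Floating
#' point values are stored as 17-significant-digit decimal strings, which
#' round-trip IEEE doubles exactly: a written-then-read model reproduces
#' every table bit for bit, so reloaded models score identically to the
#' originals.
#'
#' @param model A fitted `fp_model`.
#' @param path File path for the JSON model file.
#' @return `write_fp_model()` returns `path` invisibly; `read_fp_model()`
#'   returns the restored `fp_model`.
#' @export
write_fp_model <- function(model, path) {
  stopifnot(inherits(model, "fp_model"))
  obj <- list(
    format = "lapnb-model",
    version = MODEL_FORMAT_VERSION,
    levels = model$levels,
    L = model$L,
    C = model$C,
    mode = model$mode,
    K = if (is.null(model$K)) NULL else num_out(model$K),
    counts = list(
      N = model$counts$N,
      N_class = model$counts$N_class,
      N_present = as.vector(model$counts$N_present),
      N_feat = as.vector(model$counts$N_feat),
      features = colnames(model$counts$N_present)
    ),
    hyper = list(alpha = num_out(model$hyper$alpha), beta = num_out(model$hyper$beta)),
    prior = list(mode = model$prior$mode, probs = num_out(model$prior$probs)),
    log_xi = num_out(as.vector(model$log_xi)),
    log_nu = if (is.null(model$log_nu)) NULL else num_out(as.vector(model$log_nu))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fp_model
#' @export
read_fp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lapnb-model")) {
    rlang::abort(sprintf("'%s' is not a lapnb model file", path),
      class = "lapnb_format_error"
    )
  }
  if (obj$version > MODEL_FORMAT_VERSION) {
    rlang::abort(sprintf("model format version %s is newer than this package supports", obj$version),
      class = "lapnb_format_error"
    )
  }
  C <- as.integer(obj$C)
  L <- as.integer(obj$L)
  shape <- function(v) matrix(v, nrow = C, ncol = L, dimnames = list(obj$levels, obj$counts$features))
  counts <- structure(
    list(
      N = as.integer(obj$counts$N),
      N_class = as.integer(obj$counts$N_class),
      N_present = shape(as.integer(obj$counts$N_present)),
      N_feat = as.integer(obj$counts$N_feat),
      C = C, L = L, levels = obj$levels
    ),
    class = "fp_counts"
  )
  hyper <- beta_hyper(num_in(obj$hyper$alpha), num_in(obj$hyper$beta), C = C)
  prior <- new_fp_prior(num_in(obj$prior$probs), obj$prior$mode)
  log_xi <- shape(num_in(obj$log_xi))
  log_nu <- if (is.null(obj$log_nu)) NULL else shape(num_in(obj$log_nu))
  structure(
    list(
      counts = counts, hyper = hyper, prior = prior, mode = obj$mode,
      K = if (is.null(obj$K)) NULL else num_in(obj$K),
      xi = exp(log_xi), nu = if (is.null(log_nu)) NULL else exp(log_nu),
      log_xi = log_xi, log_nu = log_nu,
      levels = obj$levels, L = L, C = C
    ),
    class = "fp_model"
  )
}

#' Serialize a condition report
#'
#' Writes the per-compound condition verdicts and the dataset-level summary
#' as JSON (machine-readable, thresholds echoed for provenance) and,
#' optionally, a plain-text table.
#'
#' @param report An `fp_conditions` object.
#' @param path Path for the JSON report.
#' @param txt_path Optional path for a human-readable text summary.
#' @return `path`, invisibly.
#' @export
write_fp_report <- function(report, path, txt_path = NULL) {
  stopifnot(inherits(report, "fp_conditions"))
  obj <- list(
    format = "lapnb-conditions",
    version = 1L,
    verdict = report$verdict,
    agreement = report$agreement,
    thresholds = report$thresholds,
    summary = list(
      n_compounds = nrow(report$compounds),
      zero_ok = sum(report$compounds$zero_ok),
      dominance_ok = sum(report$compounds$dominance_ok),
      constancy_ok = sum(report$compounds$constancy_ok),
      n_disagreeing = sum(!report$compounds$agree)
    ),
    compounds = report$compounds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
    utils::write.table(as.data.frame(report$compounds),
      con, sep = "\t",
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}
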