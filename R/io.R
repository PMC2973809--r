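# File formats: tidy TSV for pairwise observations (long format, since
# real pairwise FISH data are ragged -- per-pair sample sizes can span two
# orders of magnitude), JSON for models.

PAIR_TABLE_COLS <- c("cell_id", "gene_a", "gene_b", "count_a", "count_b")

#' Write a pairwise observation set as tidy TSV
#'
#' One row per cell: `cell_id`, `gene_a`, `gene_b`, `count_a`, `count_b`,
#' preceded by comment lines recording the format version, the regime tag
#' and (for simulated data) the seed.  With `sidecar = TRUE` the
#' generating model, when present, is written to `<path>.model.json` so
#' recovery experiments are self-contained.
#'
#' @param data a `pair_obs` tibble.
#' @param path output file path.
#' @param sidecar also write the generating model as JSON (default `TRUE`
#'   when a model is attached).
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(data, path,
                             sidecar = !is.null(pair_obs_model(data))) {
  header <- c(
    "# snapdyn pair-table v1",
    paste0("# regime=", pair_obs_regime(data)),
    if (!is.null(attr(data, "seed"))) paste0("# seed=", attr(data, "seed"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(PAIR_TABLE_COLS, collapse = "\t"), con)
  df <- as_tibble(data)[PAIR_TABLE_COLS]
  lines <- do.call(paste, c(lapply(df, format_plain), list(sep = "\t")))
  writeLines(lines, con)
  if (sidecar && !is.null(pair_obs_model(data))) {
    write_model_json(pair_obs_model(data), paste0(path, ".model.json"))
  }
  invisible(path)
}

format_plain <- function(x) {
  if (is.numeric(x)) {
    format(x, trim = TRUE, scientific = FALSE, digits = 15)
  } else {
    as.character(x)
  }
}

#' Read a pairwise observation set from tidy TSV
#'
#' Expects the format written by [write_pair_table()] (and the shape of
#' published pairwise FISH tables: one row per fixed cell, the two probed
#' genes, and their two counts).  Genes are indexed in order of first
#' appearance.  Malformed rows are reported with their line numbers.
#'
#' @param path input file path.
#' @param regime regime tag override; by default taken from the header
#'   comment, falling back to `"continuous"` if counts are non-integer
#'   and `"bursty_count"` otherwise.
#' @return A `pair_obs` tibble.
#' @export
read_pair_table <- function(path, regime = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty file")
  is_comment <- startsWith(lines, "#")
  header_regime <- sub("^# regime=", "", grep("^# regime=", lines, value = TRUE))
  body_idx <- which(!is_comment & nzchar(lines))
  if (length(body_idx) < 2) abort("no data rows found")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, PAIR_TABLE_COLS)) {
    abort(paste0(
      "unexpected columns: ", paste(header, collapse = ", "),
      " (expected ", paste(PAIR_TABLE_COLS, collapse = ", "), ")"
    ))
  }
  data_idx <- body_idx[-1]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad_len <- lengths(fields) != 5L
  if (any(bad_len)) {
    abort(paste0(
      "malformed row(s) at line(s): ",
      paste(head(data_idx[bad_len], 5), collapse = ", ")
    ))
  }
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  ca <- suppressWarnings(as.numeric(m[, 4]))
  cb <- suppressWarnings(as.numeric(m[, 5]))
  bad_num <- is.na(ca) | is.na(cb)
  if (any(bad_num)) {
    abort(paste0(
      "non-numeric count(s) at line(s): ",
      paste(head(data_idx[bad_num], 5), collapse = ", ")
    ))
  }
  bad_neg <- ca < 0 | cb < 0
  if (any(bad_neg)) {
    abort(paste0(
      "negative count(s) at line(s): ",
      paste(head(data_idx[bad_neg], 5), collapse = ", ")
    ))
  }
  genes <- unique(as.vector(t(m[, 2:3])))
  regime <- regime %||%
    (if (length(header_regime)) header_regime[1] else NULL) %||%
    (if (any(ca != floor(ca) | cb != floor(cb))) "continuous" else "bursty_count")
  new_pair_obs(
    tibble(
      cell_id = m[, 1], gene_a = m[, 2], gene_b = m[, 3],
      count_a = ca, count_b = cb
    ),
    genes = genes, regime = regime
  )
}

#' Serialize models to and from JSON
#'
#' Writes any of the three model families to a schema-versioned JSON file;
#' `read_model_json()` reconstructs the model (round-trip reproduces every
#' parameter to better than 1e-12 relative precision, the fidelity of
#' decimal serialization).
#'
#' @param model a model object.
#' @param path file path.
#' @return `write_model_json()`: `path`, invisibly; `read_model_json()`:
#'   the model.
#' @export
write_model_json <- function(model, path) {
  payload <- if (inherits(model, "continuous_cycle_model")) {
    list(
      schema = "snapdyn-model/1", family = "continuous_cycle",
      period = model$period, genes = model$genes,
      baseline = model$baseline, amplitude = model$amplitude,
      phase = model$phase, noise_sd = model$noise_sd
    )
  } else if (inherits(model, "burst_cycle_model")) {
    list(
      schema = "snapdyn-model/1", family = "burst_cycle",
      period = model$period, genes = model$genes,
      mean_prob = model$mean_prob,
      amplitude = model$amplitude, phase = model$phase,
      global_noise_sd = model$global_noise_sd,
      amplitude_locked = model$amplitude_locked
    )
  } else if (inherits(model, "switch_model")) {
    list(
      schema = "snapdyn-model/1", family = "switch",
      genes = model$genes, state_prob = model$state_prob,
      burst_prob = model$burst_prob
    )
  } else {
    abort("unsupported model class")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "snapdyn-model/1")) {
    abort("unrecognized model schema")
  }
  switch(x$family,
    continuous_cycle = continuous_cycle_model(
      baseline = x$baseline, amplitude = x$amplitude, phase = x$phase,
      noise_sd = x$noise_sd, period = x$period, genes = x$genes
    ),
    burst_cycle = burst_cycle_model(
      mean_prob = x$mean_prob,
      amplitude = if (isTRUE(x$amplitude_locked)) NULL else as.matrix(x$amplitude),
      phase = as.matrix(x$phase),
      global_noise_sd = x$global_noise_sd,
      amplitude_locked = isTRUE(x$amplitude_locked),
      period = x$period, genes = x$genes
    ),
    switch = switch_model(
      state_prob = x$state_prob, burst_prob = as.matrix(x$burst_prob),
      genes = x$genes
    ),
    abort("unrecognized model family")
  )
}
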