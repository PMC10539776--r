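# Tab-separated interchange files with '#' metadata headers.  One dialect
# for all curve/table types; numeric parsing is locale-independent (dot
# decimal separator only).

#' Write a data table with metadata header
#'
#' Writes tab-separated text with `# key: value` metadata lines before the
#' header row.  Numeric columns are written at full precision.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list/character of metadata values.
#' @return `path`, invisibly.
#' @export
write_table_meta <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a data table with metadata header
#'
#' Counterpart of [write_table_meta()].  A `schema` (character vector of
#' required column names) is checked against the header; missing or extra
#' columns raise an error naming them.  Malformed numeric cells raise an
#' error with the offending line number.
#'
#' @param path Input path.
#' @param schema Required column names, or `NULL` to accept any.
#' @param numeric_cols Columns that must parse as numbers; defaults to all
#'   schema columns except `proton` and `nucleus`.
#' @return A tibble; metadata lines are attached as attribute `"meta"`.
#' @export
read_table_meta <- function(path, schema = NULL, numeric_cols = NULL) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta_lines <- sub("^\\s*#\\s*", "", lines[is_meta])
  meta <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- kv[3]
  }
  body_idx <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body_idx) < 2) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!is.null(schema)) {
    missing <- setdiff(schema, header)
    extra <- setdiff(header, schema)
    if (length(missing) > 0 || length(extra) > 0) {
      stop("schema mismatch in ", path,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  rows <- body_idx[-1]
  cells <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad_len <- lengths(cells) != length(header)
  if (any(bad_len)) {
    stop("wrong number of fields on line ", rows[which(bad_len)[1]],
         " of ", path, call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- header
  if (is.null(numeric_cols)) {
    numeric_cols <- setdiff(header, c("proton", "nucleus", "model"))
  }
  for (cn in intersect(numeric_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) & !all(is.na(df[[cn]]))) {
      bad <- which(is.na(v) & !is.na(df[[cn]]))[1]
      stop(sprintf("malformed numeric value '%s' in column '%s', line %d of %s",
                   df[[cn]][bad], cn, rows[bad + 1L] - 1L + 1L, path),
           call. = FALSE)
    }
    df[[cn]] <- v
  }
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Read or write CIDNP curves, NMRD tables and transfer profiles
#'
#' Typed wrappers around [read_table_meta()] / [write_table_meta()] with the
#' package's column schemas: CIDNP curves (`field_T`, `polarization`,
#' `nucleus`), NMRD tables (`proton`, `B_T`, `T1_s`, optionally `T1_err_s`),
#' decay tables (`proton`, `B_T`, `tau_vd_s`, `intensity`) and transfer
#' profiles (`t_s`, `B_T`).
#'
#' @param x Object to write.
#' @param path File path.
#' @param meta Extra metadata for the header.
#' @return Readers return tibbles (curves as [cidnp_curve()]); writers
#'   return `path` invisibly.
#' @name cidnp_io
NULL

#' @rdname cidnp_io
#' @export
write_cidnp_curve <- function(x, path, meta = list()) {
  stopifnot(all(c("field_T", "polarization") %in% names(x)))
  meta <- c(list(type = "cidnp_curve",
                 source = attr(x, "source") %||% "unknown"), meta)
  cols <- intersect(c("field_T", "polarization", "nucleus", "uncertainty",
                      "attenuation"), names(x))
  write_table_meta(as.data.frame(x)[cols], path, meta)
}

#' @rdname cidnp_io
#' @export
read_cidnp_curve <- function(path) {
  df <- read_table_meta(path)
  stopifnot(all(c("field_T", "polarization") %in% names(df)))
  src <- attr(df, "meta")$source %||% "observed"
  out <- cidnp_curve(df$field_T, df$polarization,
                     nucleus = if ("nucleus" %in% names(df)) df$nucleus else "A8",
                     uncertainty = if ("uncertainty" %in% names(df)) df$uncertainty else NULL,
                     source = if (identical(src, "simulated")) "simulated" else "observed")
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' @rdname cidnp_io
#' @export
write_nmrd_table <- function(x, path, meta = list()) {
  stopifnot(all(c("proton", "B_T", "T1_s") %in% names(x)))
  write_table_meta(as.data.frame(x), path, c(list(type = "nmrd"), meta))
}

#' @rdname cidnp_io
#' @export
read_nmrd_table <- function(path) {
  read_table_meta(path, numeric_cols = c("B_T", "T1_s", "T1_err_s"))
}

#' @rdname cidnp_io
#' @export
write_decay_table <- function(x, path, meta = list()) {
  stopifnot(all(c("proton", "B_T", "tau_vd_s", "intensity") %in% names(x)))
  write_table_meta(as.data.frame(x), path, c(list(type = "decays"), meta))
}

#' @rdname cidnp_io
#' @export
read_decay_table <- function(path) {
  read_table_meta(path, schema = c("proton", "B_T", "tau_vd_s", "intensity"))
}

#' @rdname cidnp_io
#' @export
write_transfer_profile <- function(x, path, meta = list()) {
  stopifnot(all(c("t_s", "B_T") %in% names(x)))
  write_table_meta(as.data.frame(x)[c("t_s", "B_T")], path,
                   c(list(type = "transfer_profile",
                          start_field = attr(x, "start_field") %||% x$B_T[1]),
                     meta))
}

#' @rdname cidnp_io
#' @export
read_transfer_profile <- function(path) {
  df <- read_table_meta(path, schema = c("t_s", "B_T"))
  out <- transfer_profile(df$t_s, df$B_T,
                          start_field = as.numeric(attr(df, "meta")$start_field))
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the package's stages end to end in a working directory:
#' (1) generate synthetic NMRD decays and an observed CIDNP curve from a
#' chosen truth distribution, (2) fit per-proton T1 values and dispersion
#' parameters, (3) deconvolve the observed curve for transfer losses,
#' (4) simulate candidate distributions and (5) rank them against the
#' deconvolved curve.  All artefacts are written as tab-separated files
#' with metadata headers (including the seed and the exchange convention),
#' plus a `manifest.txt`.
#'
#' @param out_dir Output directory (created if needed).
#' @param model A [biradical_model()].
#' @param grid A [radial_grid()].
#' @param truth Distribution preset generating the synthetic observation.
#' @param candidates Preset names to rank.
#' @param cfg A [synthetic_study_config()].
#' @param fields CIDNP field grid, T.
#' @param nmrd_fields Relaxation fields for the synthetic NMRD stage, T.
#' @param seed Seed for all generators.
#'
#' @return Invisibly, a list with the manifest, the [rank_models()] report
#'   and paths of all written files.
#' @export
run_pipeline <- function(out_dir,
                         model = biradical_model(),
                         grid = radial_grid(),
                         truth = "sim1",
                         candidates = c("sim1", "sim2", "sim3", "sim4"),
                         cfg = synthetic_study_config(),
                         fields = log_field_grid(1e-4, 9.4, 31),
                         nmrd_fields = 10^seq(log10(0.5), log10(16.4), length.out = 12),
                         seed = cfg$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  meta0 <- list(seed = seed,
                exchange_convention = model$exchange$convention)

  # synthetic truth curve and observation
  true_curve <- field_sweep(fields, model = model, grid = grid,
                            dist = distribution_preset(truth))
  obs <- gen_observed_cidnp(true_curve, cfg, seed = seed)
  write_cidnp_curve(true_curve, p("true_curve.tsv"), meta0)
  write_cidnp_curve(obs, p("observed.tsv"), meta0)

  # synthetic NMRD stage
  decays <- gen_nmrd_decays(cfg, nmrd_fields, seed = seed)
  write_decay_table(decays, p("decays.tsv"), meta0)
  nmrd <- fit_decay_table(decays)
  write_nmrd_table(nmrd, p("nmrd.tsv"), meta0)
  disp <- fit_dispersion_table(nmrd, B_min = 0.56, B_max = 16.44)
  write_table_meta(disp, p("nmrd_params.tsv"), c(list(type = "nmrd_params"),
                                                 meta0))

  # deconvolution using the fitted A8 dispersion
  a8 <- disp[disp$proton == "A8", ]
  rates <- list(R1 = a8$R1, R1inf = a8$R1inf, tau_c = a8$tau_c)
  corrected <- deconvolve_curve(obs, shuttle_profiles(cfg), rates)
  write_cidnp_curve(corrected, p("corrected.tsv"), meta0)

  # model ranking
  report <- rank_models(corrected, as.list(candidates), model = model,
                        grid = grid)
  write_table_meta(report, p("qreport.tsv"), c(list(type = "q_report"),
                                               meta0))

  files <- c("true_curve.tsv", "observed.tsv", "decays.tsv", "nmrd.tsv",
             "nmrd_params.tsv", "corrected.tsv", "qreport.tsv")
  manifest <- c(
    sprintf("cidnpr pipeline manifest"),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("cidnpr"))),
    sprintf("seed: %d", seed),
    sprintf("truth: %s", truth),
    sprintf("exchange_convention: %s", model$exchange$convention),
    sprintf("best_model: %s", report$model[1]),
    paste0("file: ", files)
  )
  writeLines(manifest, p("manifest.txt"))
  invisible(list(manifest = manifest, report = report,
                 files = vapply(files, p, "")))
}
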