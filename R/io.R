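# File formats: CSVs are comma-separated UTF-8 with a header row and "."
# decimals, preceded by "# key=value" provenance comment lines carrying the
# run configuration. JSON files embed the same config as a "config" field.

.meta_lines <- function(meta) {
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  vapply(names(meta), function(k) {
    paste0("# ", k, "=", paste(format(meta[[k]], digits = 12), collapse = ","))
  }, character(1L))
}

.write_csv <- function(dt, path, meta = list()) {
  lines <- .meta_lines(meta)
  if (length(lines)) {
    writeLines(lines, path)
    data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

.read_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "# ")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^# ", "", ln)
    pos <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1L, pos - 1L)]] <- substring(kv, pos + 1L)
  }
  dt <- data.table::fread(text = lines[!is_meta])
  attr(dt, "meta") <- meta
  dt
}

#' Read or write a free-energy profile as JSON
#'
#' Flat schema: `{"mechanism": "simple"|"complex", "temperature_K":
#' number, "energies": {state: kcal/mol}}`.
#'
#' @param profile An `fe_profile`.
#' @param path File path.
#' @return `write_profile_json` returns `path` invisibly;
#'   `read_profile_json` returns an `fe_profile`.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  jsonlite::write_json(
    list(mechanism = profile$mechanism,
         temperature_K = profile$temperature,
         energies = as.list(profile$energies)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mechanism", "temperature_K", "energies")) {
    if (is.null(x[[f]])) stop("profile JSON missing field: ", f, call. = FALSE)
  }
  energy_profile(x$mechanism, unlist(x$energies), x$temperature_K)
}

.run_meta <- function(obj) {
  list(mechanism = obj$mechanism, n = obj$n,
       bounds = obj$bounds, seed = obj$seed,
       temperature_K = obj$temperature)
}

#' Write a mutation library to CSV
#'
#' Columns: `id` and one `dG_<state>` column per state (kcal/mol).
#' Config (mechanism, n, bounds, seed) is embedded as `# key=value`
#' comment lines.
#'
#' @param mutations A `mutation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations_csv <- function(mutations, path) {
  stopifnot(inherits(mutations, "mutation_set"))
  dt <- data.table::as.data.table(mutations$dG)
  data.table::setnames(dt, paste0("dG_", colnames(mutations$dG)))
  dt <- cbind(data.table::data.table(id = seq_len(mutations$n)), dt)
  .write_csv(dt, path, list(mechanism = mutations$mechanism,
                            n = mutations$n, bounds = mutations$bounds,
                            seed = mutations$seed))
}

#' Read a mutation library written by [write_mutations_csv()]
#'
#' @param path CSV path.
#' @return A `mutation_set`.
#' @export
read_mutations_csv <- function(path) {
  dt <- .read_csv(path)
  meta <- attr(dt, "meta")
  cols <- grep("^dG_", names(dt), value = TRUE)
  dG <- as.matrix(dt[, cols, with = FALSE])
  colnames(dG) <- sub("^dG_", "", cols)
  mech <- meta$mechanism %||% "simple"
  dG <- dG[, .states_for(mech), drop = FALSE]
  structure(
    list(dG = dG, mechanism = mech,
         bounds = if (!is.null(meta$bounds))
           as.numeric(strsplit(meta$bounds, ",")[[1L]]) else c(NA_real_, NA_real_),
         seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NULL,
         n = nrow(dG)),
    class = "mutation_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a variant table to CSV
#'
#' One row per variant: `wt`, `m<i>` for singles, `m<i>_m<j>` for
#' unordered pairs. Columns `kcat_per_s`, `KM_M`, `KD_M`,
#' `efficiency_per_M_per_s`; pairs additionally carry the
#' multiplicative-null `pred_*` columns.
#'
#' @param table A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_csv <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  csv_cols <- c(kcat_per_s = "k_cat", KM_M = "K_M", KD_M = "K_D",
                efficiency_per_M_per_s = "efficiency")
  wt_row <- data.table::as.data.table(
    c(list(variant_id = "wt"), as.list(unclass(table$wt)[csv_cols])))
  data.table::setnames(wt_row, c("variant_id", names(csv_cols)))
  s <- data.table::copy(table$singles)
  s[, variant_id := paste0("m", id)]
  s[, id := NULL]
  data.table::setnames(s, csv_cols, names(csv_cols))
  p <- data.table::copy(table$pairs)
  p[, variant_id := paste0("m", i, "_m", j)]
  p[, c("i", "j") := NULL]
  data.table::setnames(p, csv_cols, names(csv_cols))
  data.table::setnames(p, paste0("pred_", csv_cols),
                       paste0("pred_", names(csv_cols)))
  dt <- data.table::rbindlist(list(wt_row, s, p), fill = TRUE)
  data.table::setcolorder(dt, "variant_id")
  .write_csv(dt, path, .run_meta(table))
}

#' Write per-pair epistasis records to CSV
#'
#' @param records Output of [epistasis_records()].
#' @param path Output path.
#' @param meta Optional named list embedded as comment lines.
#' @return `path`, invisibly.
#' @export
write_epistasis_csv <- function(records, path, meta = list()) {
  dt <- data.table::copy(data.table::as.data.table(records))
  dt[, pair_id := paste0("m", i, "_m", j)]
  dt[, c("i", "j") := NULL]
  data.table::setcolorder(dt, "pair_id")
  .write_csv(dt, path, meta)
}

#' Write an epistasis summary to JSON
#'
#' Nested per-parameter prevalence, class shares, sign shares and raw
#' counts, plus the run configuration (seed, n, bounds, mechanism,
#' temperature).
#'
#' @param summary An `epistasis_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "epistasis_summary"))
  payload <- list(
    parameters = lapply(summary$parameters, function(s) {
      list(prevalence_pct = as.list(s$prevalence_pct),
           class_pct = as.list(s$class_pct),
           sign_pct = as.list(s$sign_pct),
           counts = as.list(s$counts))
    }),
    config = list(mechanism = summary$mechanism, n = summary$n,
                  n_pairs = summary$n_pairs, bounds = summary$bounds,
                  seed = summary$seed, thresholds = summary$thresholds,
                  temperature_K = summary$temperature))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an experimental double-mutant cycle from JSON or CSV
#'
#' JSON schema: `{"mechanism": ..., "variants": {"wt": {"k1": ...,
#' "k_minus1": ..., "k2": ..., "k_minus2": ..., "k3": ...}, "mutA": ...,
#' "mutB": ..., "double": ...}, "measured": {variant: {"k_cat": ...,
#' "K_M": ..., "efficiency": ...}}, "bound_flags": {variant: [rate
#' names]}}` (`measured` and `bound_flags` optional; `k_minus2`/`k3`
#' optional for simple mechanisms). CSV: one row per variant with columns
#' `variant`, `k1`, `k_minus1`, `k2`, optional `k_minus2`, `k3`, optional
#' `is_bound_<rate>` logicals and `measured_<parameter>` values.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return An `experimental_variant_set`.
#' @export
read_experiment <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) ||
      !file.exists(path)) {
    stop("experiment file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .read_experiment_json(path)
  } else {
    .read_experiment_csv(path)
  }
}

.RATE_NAMES_ALL <- c("k1", "k_minus1", "k2", "k_minus2", "k3")
.VARIANT_NAMES <- c("wt", "mutA", "mutB", "double")

.read_experiment_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$variants)) stop("experiment JSON missing field: variants",
                                call. = FALSE)
  missing <- setdiff(.VARIANT_NAMES, names(x$variants))
  if (length(missing)) {
    stop("experiment JSON missing variant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mech <- x$mechanism
  variants <- lapply(x$variants[.VARIANT_NAMES], function(v) {
    rate_constants(unlist(v), mech)
  })
  measured <- if (!is.null(x$measured)) lapply(x$measured, unlist)
  bound_flags <- if (!is.null(x$bound_flags)) lapply(x$bound_flags, unlist)
  experimental_variant_set(variants$wt, variants$mutA, variants$mutB,
                           variants$double, measured, bound_flags)
}

.read_experiment_csv <- function(path) {
  dt <- .read_csv(path)
  if (!"variant" %in% names(dt)) {
    stop("experiment CSV missing column: variant", call. = FALSE)
  }
  missing <- setdiff(.VARIANT_NAMES, dt$variant)
  if (length(missing)) {
    stop("experiment CSV missing variant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mech <- attr(dt, "meta")$mechanism
  rate_cols <- intersect(.RATE_NAMES_ALL, names(dt))
  get_row <- function(v) dt[dt$variant == v, ][1L, ]
  variants <- lapply(.VARIANT_NAMES, function(vn) {
    row <- get_row(vn)
    k <- unlist(row[, rate_cols, with = FALSE])
    rate_constants(k[!is.na(k)], mech)
  })
  names(variants) <- .VARIANT_NAMES
  meas_cols <- grep("^measured_", names(dt), value = TRUE)
  measured <- NULL
  if (length(meas_cols)) {
    measured <- lapply(.VARIANT_NAMES, function(vn) {
      row <- get_row(vn)
      m <- unlist(row[, meas_cols, with = FALSE])
      names(m) <- sub("^measured_", "", names(m))
      m[!is.na(m)]
    })
    names(measured) <- .VARIANT_NAMES
    measured <- Filter(length, measured)
    if (!length(measured)) measured <- NULL
  }
  bound_cols <- grep("^is_bound_", names(dt), value = TRUE)
  bound_flags <- NULL
  if (length(bound_cols)) {
    bound_flags <- lapply(.VARIANT_NAMES, function(vn) {
      row <- get_row(vn)
      fl <- unlist(row[, bound_cols, with = FALSE])
      sub("^is_bound_", "", names(fl)[!is.na(fl) & fl != 0])
    })
    names(bound_flags) <- .VARIANT_NAMES
    bound_flags <- Filter(length, bound_flags)
    if (!length(bound_flags)) bound_flags <- NULL
  }
  experimental_variant_set(variants$wt, variants$mutA, variants$mutB,
                           variants$double, measured, bound_flags)
}

#' Write a correction report to JSON
#'
#' @param report A `correction_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "correction_report"))
  payload <- list(
    mechanism = report$mechanism,
    parameters = lapply(report$parameters, as.list),
    expected_double_rates = as.list(report$expected_rates$k),
    specific_epistasis = as.list(report$specific_epistasis),
    kinetic_parameter_epistasis = list(
      null = as.list(report$null),
      corrected_null = as.list(report$corrected_null),
      observed = as.list(report$observed),
      nonspecific_epsilon = as.list(report$nonspecific_epsilon),
      apparent_epsilon = as.list(report$apparent_epsilon),
      corrected_epsilon = as.list(report$corrected_epsilon)),
    fold_errors = report$fold_errors,
    warnings = report$warnings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Generate small deterministic fixtures
#'
#' Writes, under `dir`: the wild-type profiles (`simple_wt.json`,
#' `complex_wt.json`), a 50-mutation simple-mechanism library and its
#' variant/epistasis/summary files, and a synthetic experimental
#' double-mutant cycle (`experiment.json`, plus `report.json`) in which a
#' known 5-fold specific epistasis is injected into k2 of the double
#' mutant so the correction workflow's recovery can be checked.
#'
#' @param seed Integer seed (drives both the library and the synthetic
#'   experiment).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_profile_json(default_profile("simple_wt"), p("simple_wt.json"))
  write_profile_json(default_profile("complex_wt"), p("complex_wt.json"))

  sim <- simulate_epistasis("simple", n = 50, seed = seed)
  write_mutations_csv(sim$mutations, p("mutations.csv"))
  write_variants_csv(sim$table, p("variants.csv"))
  write_epistasis_csv(epistasis_records(sim$table), p("epistasis.csv"),
                      .run_meta(sim$table))
  write_summary_json(sim$summary, p("summary.json"))

  # Synthetic double-mutant cycle: singles from two random additive
  # perturbations; double additive except a 5-fold boost injected on k2.
  profile <- default_profile("simple_wt")
  muts <- sample_mutations(2L, c(-2, 2), "simple", seed = seed + 1L)
  wt_r <- rates_from_profile(profile)
  a_r <- rates_from_profile(apply_effects(profile, mutation_effect(muts, 1L)))
  b_r <- rates_from_profile(apply_effects(profile, mutation_effect(muts, 2L)))
  d_k <- expected_double_rates(wt_r, a_r, b_r)$k
  d_k[["k2"]] <- d_k[["k2"]] * 5
  d_r <- rate_constants(d_k, "simple")
  exper <- list(
    mechanism = "simple",
    variants = list(wt = as.list(wt_r$k), mutA = as.list(a_r$k),
                    mutB = as.list(b_r$k), double = as.list(d_r$k)),
    config = list(seed = seed, injected_specific_k2_fold = 5))
  jsonlite::write_json(exper, p("experiment.json"), auto_unbox = TRUE,
                       digits = NA)
  rep <- correction_report(read_experiment(p("experiment.json")))
  write_report_json(rep, p("report.json"))

  files <- c(simple_wt = p("simple_wt.json"), complex_wt = p("complex_wt.json"),
             mutations = p("mutations.csv"), variants = p("variants.csv"),
             epistasis = p("epistasis.csv"), summary = p("summary.json"),
             experiment = p("experiment.json"), report = p("report.json"))
  invisible(files)
}
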