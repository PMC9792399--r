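#' Write a photon trace to the CSV trace dialect
#'
#' Plain-text interchange format: two comment lines carrying the
#' observation window (`# t_start=...`, `# t_end=...`), then a
#' `time_s,channel` header and one row per photon with decimal seconds at
#' full double precision (round-trips exactly to at least 12 significant
#' digits).
#'
#' @param trace A [photon_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  win <- trace_window(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# t_start=%.17g", win["t_start"]),
    sprintf("# t_end=%.17g", win["t_end"]),
    "time_s,channel"), con)
  if (nrow(trace)) {
    writeLines(sprintf("%.17g,%d", trace$time_s, trace$channel), con)
  }
  invisible(path)
}

#' Read a photon trace
#'
#' Reads the CSV trace dialect written by [write_trace()]. Detector ids
#' in the file are mapped to the semantic channels (1 = acceptor,
#' 2 = donor) through `detector_map`; unknown ids and nonmonotone
#' timestamps are rejected with the offending row.
#'
#' @param path File path.
#' @param format Only `"csv"` is supported in this build; requesting
#'   `"photon-hdf5"` raises an informative error.
#' @param detector_map Named integer vector mapping file detector ids to
#'   channels; default identity `c("1" = 1, "2" = 2)`.
#'
#' @return A [photon_trace()].
#' @export
read_trace <- function(path, format = c("csv", "photon-hdf5"),
                       detector_map = c("1" = 1L, "2" = 2L)) {
  format <- match.arg(format)
  if (format == "photon-hdf5") {
    stop("photon-hdf5 reading is not available in this build; ",
         "convert to the CSV trace dialect (see ?write_trace)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 2L)
  win <- vapply(c("t_start", "t_end"), function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
    if (!length(hit)) {
      stop(sprintf("missing window record '# %s=' in %s", key, path),
           call. = FALSE)
    }
    as.numeric(sub(".*=", "", hit[1]))
  }, numeric(1))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "channel") %in% names(df))) {
    stop("trace file must have columns time_s,channel", call. = FALSE)
  }
  ids <- as.character(df$channel)
  unknown <- !ids %in% names(detector_map)
  if (any(unknown)) {
    stop(sprintf("unknown detector id '%s' at row %d",
                 ids[which(unknown)[1]], which(unknown)[1]), call. = FALSE)
  }
  dup <- duplicated(df$time_s)
  if (any(dup)) {
    stop(sprintf("duplicate timestamp at row %d", which(dup)[1]),
         call. = FALSE)
  }
  photon_trace(df$time_s, detector_map[ids], win[1], win[2])
}

#' Provenance record for an output file
#'
#' @param config Any serializable configuration object.
#' @param seed Integer seed of the run (or `NULL`).
#' @return List with package version, configuration hash, seed and
#'   creation time.
#' @export
provenance_record <- function(config, seed = NULL) {
  list(package = "fretjump",
       version = as.character(utils::packageVersion("fretjump")),
       config_hash = rlang::hash(config),
       seed = seed,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a posterior chain with its metadata sidecar
#'
#' The chain table goes to `path` as CSV (one row per sweep, columns in
#' the stored order); priors, sampler configuration, fixed photophysics,
#' acceptance counters and a provenance record go to `<path>.meta.json`.
#'
#' @param chain A `"fret_chain"`.
#' @param path Output CSV path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("refusing to overwrite ", path, " without force = TRUE",
         call. = FALSE)
  }
  utils::write.csv(tibble::as_tibble(chain), path, row.names = FALSE)
  meta <- list(
    prior = unclass(attr(chain, "prior")),
    config = unclass(attr(chain, "config")),
    fixed = attr(chain, "fixed"),
    acceptance = attr(chain, "acceptance"),
    provenance = provenance_record(
      list(prior = unclass(attr(chain, "prior")),
           config = unclass(attr(chain, "config"))),
      seed = attr(chain, "config")$seed)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a posterior chain written by [write_chain()]
#'
#' @param path Chain CSV path (the `.meta.json` sidecar must sit next to
#'   it).
#' @return A `"fret_chain"` with configuration attributes restored.
#' @export
read_chain <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else NULL
  prior <- config <- fixed <- NULL
  if (!is.null(meta)) {
    pr <- meta$prior
    prior <- structure(list(
      m_max = as.integer(pr$m_max),
      lambda_ref = unlist(pr$lambda_ref),
      alpha = unlist(pr$alpha),
      gamma = pr$gamma, load_prob = pr$load_prob), class = "prior_config")
    cf <- meta$config
    config <- structure(list(
      n_sweeps = as.integer(cf$n_sweeps), burn_in = as.integer(cf$burn_in),
      var_a = unlist(cf$var_a), var_b = unlist(cf$var_b),
      kappa = cf$kappa, fixed_loads = isTRUE(cf$fixed_loads),
      seed = cf$seed, verbose = FALSE), class = "sampler_config")
    fixed <- meta$fixed
  }
  structure(df, class = c("fret_chain", class(df)),
            prior = prior, config = config, fixed = fixed,
            acceptance = meta$acceptance)
}

#' Write a posterior summary report
#'
#' Structured JSON: state-count histogram, per-state medians and 95%
#' intervals, the median system-rate matrix, steady-state populations,
#' optional photon-budget table, and a provenance record.
#'
#' @param summary A `"fret_summary"`.
#' @param path Output JSON path.
#' @param budget Optional tibble from [photon_budget_index()].
#' @param seed Seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, budget = NULL, seed = NULL) {
  report <- list(
    state_count = summary$state_count,
    map_states = summary$map_states,
    dimension = summary$dimension,
    per_state = summary$per_state,
    median_matrix = summary$median_matrix,
    steady_state = summary$steady_state,
    n_sweeps_used = summary$n_sweeps_used,
    budget = budget,
    provenance = provenance_record(summary["dimension"], seed)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

# ---- run configuration ------------------------------------------------

run_config_keys <- list(
  calibration = c("rcm", "phi_d", "phi_a", "bg", "lambda_d", "lambda_a",
                  "lambda_direct", "lambda_back"),
  prior = c("m_max", "lambda_ref_ex", "lambda_ref_fret", "lambda_ref_sys",
            "alpha", "alpha_ex", "gamma"),
  sampler = c("n_sweeps", "burn_in", "fixed_loads", "seed"),
  simulation = c("lambda_ex", "efficiency", "escape", "lambda_sys",
                 "duration", "photons")
)

#' Read and validate a run configuration file
#'
#' YAML with up to four blocks — `calibration` (RCM or explicit phi
#' factors, background rates, donor/acceptor relaxation rates), `prior`,
#' `sampler`, and `simulation`. Unknown keys are rejected. Returns the
#' parsed blocks together with assembled objects where possible
#' (`detection`, `prior_config`, `sampler_config`, `fixed`).
#'
#' @param path YAML file path.
#' @return Named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML leaves scientific notation without a signed exponent ("2.857e8")
  # as character; every schema value is numeric or logical, so coerce
  raw <- rapply(raw, function(x) {
    if (is.character(x)) {
      v <- suppressWarnings(as.numeric(x))
      if (!anyNA(v)) return(v)
    }
    x
  }, how = "replace")
  unknown <- setdiff(names(raw), names(run_config_keys))
  if (length(unknown)) {
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(raw)) {
    bad <- setdiff(names(raw[[blk]]), run_config_keys[[blk]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in %s block: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  out <- list(raw = raw)
  cal <- raw$calibration
  if (!is.null(cal)) {
    bg <- if (is.null(cal$bg)) c(0, 0) else as.numeric(unlist(cal$bg))
    out$detection <- if (!is.null(cal$rcm)) {
      normalize_rcm(matrix(as.numeric(unlist(cal$rcm)), 2, 2, byrow = TRUE),
                    bg = bg)
    } else if (!is.null(cal$phi_d)) {
      detection_model(as.numeric(unlist(cal$phi_d)),
                      as.numeric(unlist(cal$phi_a)), bg)
    }
    out$fixed <- fixed_phys_rates(
      lambda_d = cal$lambda_d %||% (1 / 3.5e-9),
      lambda_a = cal$lambda_a %||% cal$lambda_d %||% (1 / 3.5e-9),
      lambda_direct = cal$lambda_direct %||% 0,
      lambda_back = cal$lambda_back %||% 0)
  }
  if (!is.null(raw$prior)) {
    out$prior <- do.call(prior_config, raw$prior)
  }
  if (!is.null(raw$sampler)) {
    out$sampler <- do.call(sampler_config, raw$sampler)
  }
  out$simulation <- raw$simulation
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
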