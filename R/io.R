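#' Concentration-time profile for one subject and matrix
#'
#' @param subject Subject identifier (text).
#' @param tissue `"plasma"` or a named tissue.
#' @param route `"iv"` or `"po"`.
#' @param dose Dose in mg/kg.
#' @param times Sampling times in hours, strictly increasing.
#' @param conc Concentrations in ug/mL; `NA` marks below-LOQ observations.
#' @param loq Optional limit of quantification in ug/mL retained for BLQ points.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject, tissue, route, dose, times, conc, loq = NA_real_) {
  route <- match.arg(route, c("iv", "po"))
  stopifnot(length(times) == length(conc))
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop(sprintf("times for subject '%s' (%s) must be strictly increasing",
                 subject, tissue), call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop(sprintf("negative concentration for subject '%s' (%s)", subject, tissue),
         call. = FALSE)
  }
  if (sum(!is.na(conc)) < 2L) {
    stop(sprintf("profile for subject '%s' (%s) needs >= 2 non-missing points",
                 subject, tissue), call. = FALSE)
  }
  assert_scalar(dose, "dose", lo = 0)
  structure(
    list(subject = as.character(subject), tissue = as.character(tissue),
         route = route, dose = dose, times = as.numeric(times),
         conc = as.numeric(conc), loq = loq),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s | %s | %s %g mg/kg | %d points (%d BLQ)\n",
              x$subject, x$tissue, x$route, x$dose, length(x$times),
              sum(is.na(x$conc))))
  invisible(x)
}

#' Read concentration-time profiles from a long-format CSV file
#'
#' The file must contain the columns `subject`, `tissue`, `time_h`,
#' `conc_ug_per_mL`, `dose_mg_per_kg`, `route` (comma-separated, dot decimal,
#' one header row, one row per observation). Cells holding the token `"BLQ"`
#' are recorded as missing; if a `loq_ug_per_mL` column is present its value
#' is retained on the profile. Duplicate `(subject, tissue, time)` rows,
#' non-monotone times within a profile, and negative concentrations are
#' rejected with informative errors.
#'
#' @param path Path to the CSV file.
#' @return A named list of [conc_profile()] objects, keyed `subject.tissue`.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("profile table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject", "tissue", "time_h", "conc_ug_per_mL",
                "dose_mg_per_kg", "route")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("profile table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$time_h <- as.numeric(df$time_h)
  df$dose_mg_per_kg <- as.numeric(df$dose_mg_per_kg)
  is_blq <- toupper(trimws(df$conc_ug_per_mL)) == "BLQ"
  conc <- suppressWarnings(as.numeric(df$conc_ug_per_mL))
  if (any(!is_blq & is.na(conc))) {
    bad <- which(!is_blq & is.na(conc))
    stop("unparseable concentration value(s) at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conc[is_blq] <- NA_real_
  if (any(conc < 0, na.rm = TRUE)) {
    bad <- which(conc < 0)
    stop("negative concentration(s) at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$subject, df$tissue, sep = ".")
  dup <- duplicated(data.frame(key, df$time_h))
  if (any(dup)) {
    stop("duplicate (subject, tissue, time) row(s) at data row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  loq <- if ("loq_ug_per_mL" %in% names(df)) as.numeric(df$loq_ug_per_mL) else rep(NA_real_, nrow(df))
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    idx <- which(key == k)
    if (any(diff(rows$time_h) <= 0)) {
      stop(sprintf("non-monotone sampling times for subject '%s' (tissue '%s')",
                   rows$subject[1], rows$tissue[1]), call. = FALSE)
    }
    out[[k]] <- conc_profile(
      subject = rows$subject[1], tissue = rows$tissue[1],
      route = rows$route[1], dose = rows$dose_mg_per_kg[1],
      times = rows$time_h, conc = conc[idx],
      loq = if (all(is.na(loq[idx]))) NA_real_ else max(loq[idx], na.rm = TRUE)
    )
  }
  out
}

#' Write concentration-time profiles to a long-format CSV file
#'
#' Inverse of [read_profile_table()]: missing concentrations are written back
#' as the token `"BLQ"`, numeric values at full precision, so a write/read
#' round trip preserves every value exactly.
#'
#' @param profiles A list of `conc_profile` objects.
#' @param path Output CSV path.
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(
      subject = p$subject, tissue = p$tissue, time_h = format_full(p$times),
      conc_ug_per_mL = ifelse(is.na(p$conc), "BLQ", format_full(p$conc)),
      dose_mg_per_kg = format_full(p$dose), route = p$route,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision, locale-independent numeric formatting (round-trip safe).
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
}

#' Assemble a report bundle of named numeric results by pipeline stage
#'
#' A `report_bundle` maps stage names (e.g. `"nca"`, `"ivive"`) to tables of
#' named numeric results with unit strings, plus input provenance. Writing a
#' bundle is deterministic: stages and parameters are sorted, so re-writing
#' the same bundle produces byte-identical files regardless of insertion
#' order.
#'
#' @param provenance Named character vector of input file paths or identifiers.
#' @return An empty `report_bundle`.
#' @export
report_bundle <- function(provenance = character()) {
  structure(list(stages = list(), provenance = provenance),
            class = "report_bundle")
}

#' Add a stage of results to a report bundle
#'
#' @param bundle A [report_bundle()].
#' @param stage Unique stage name.
#' @param values Named numeric vector of results.
#' @param units Character vector of unit strings, one per value (recycled if
#'   length one).
#' @return The updated bundle.
#' @export
add_stage <- function(bundle, stage, values, units) {
  stopifnot(inherits(bundle, "report_bundle"),
            is.character(stage), length(stage) == 1L,
            is.numeric(values), !is.null(names(values)))
  if (stage %in% names(bundle$stages)) {
    stop("stage '", stage, "' is already present in the bundle", call. = FALSE)
  }
  units <- rep_len(as.character(units), length(values))
  bundle$stages[[stage]] <- data.frame(
    parameter = names(values), value = unname(values), unit = units,
    stringsAsFactors = FALSE
  )
  bundle
}

#' Write a report bundle to a stably ordered CSV file
#'
#' Columns `stage, parameter, value, unit`, sorted by stage then parameter,
#' values at full precision. An empty bundle yields a header-only file.
#'
#' @param bundle A [report_bundle()].
#' @param path Output CSV path.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (length(bundle$stages) == 0L) {
    writeLines("stage,parameter,value,unit", path)
    return(invisible(path))
  }
  stage_names <- sort(names(bundle$stages))
  rows <- lapply(stage_names, function(s) {
    tab <- bundle$stages[[s]]
    tab <- tab[order(tab$parameter), , drop = FALSE]
    data.frame(stage = s, parameter = tab$parameter,
               value = format_full(tab$value), unit = tab$unit,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
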