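#' Column schema for paired soil-wheat sample tables
#'
#' Every dataset handled by the package is a plain data frame with one row per
#' paired topsoil / wheat-grain sample. Mandatory columns are the grain and
#' total soil Cd concentrations plus the routinely measured soil properties;
#' the five Tessier Cd fractions are optional but must be present as a group
#' for speciation work. Units follow the field conventions: Cd, Zn and the Cd
#' fractions in mg/kg dry weight; Ca, Fe, Mn, P and CaCO3 in g/kg; organic
#' matter and the particle-size fractions in percent; pH unitless.
#'
#' @return A data frame with columns `column` (canonical name), `required`
#'   (logical) and `unit`.
#' @export
cd_schema <- function() {
  data.frame(
    column = c("sample_id", "soil_cd", "grain_cd", "ph", "om", "caco3",
               "clay", "silt", "sand", "ca", "fe", "mn", "p", "zn",
               "ex_cd", "ca_cd", "fm_cd", "or_cd", "re_cd"),
    required = c(rep(TRUE, 14), rep(FALSE, 5)),
    unit = c("id", "mg/kg", "mg/kg", "pH", "%", "g/kg",
             "%", "%", "%", "g/kg", "g/kg", "g/kg", "g/kg", "mg/kg",
             rep("mg/kg", 5)),
    stringsAsFactors = FALSE
  )
}

# Header aliases seen in field spreadsheets -> canonical schema names.
# Matching is case-insensitive after stripping non-alphanumerics.
.column_aliases <- c(
  "sampleid" = "sample_id", "id" = "sample_id", "sample" = "sample_id",
  "soilcd" = "soil_cd", "cdsoil" = "soil_cd", "totalcd" = "soil_cd",
  "graincd" = "grain_cd", "cdgrain" = "grain_cd", "wheatcd" = "grain_cd",
  "ph" = "ph", "om" = "om", "organicmatter" = "om",
  "caco3" = "caco3", "clay" = "clay", "silt" = "silt", "sand" = "sand",
  "ca" = "ca", "soilca" = "ca", "fe" = "fe", "soilfe" = "fe",
  "mn" = "mn", "soilmn" = "mn", "p" = "p", "soilp" = "p",
  "zn" = "zn", "soilzn" = "zn",
  "excd" = "ex_cd", "cacd" = "ca_cd", "fmcd" = "fm_cd",
  "orcd" = "or_cd", "recd" = "re_cd"
)

.fraction_cols <- c("ex_cd", "ca_cd", "fm_cd", "or_cd", "re_cd")

.normalise_header <- function(x) {
  key <- tolower(gsub("[^[:alnum:]]", "", x))
  out <- .column_aliases[key]
  ifelse(is.na(out), tolower(x), out)
}

#' Validate a soil-wheat dataset against the sample schema
#'
#' Checks the physical invariants every record must satisfy: non-negative
#' concentrations, pH within (0, 14), clay + silt + sand summing to 100
#' within `texture_tol`, unique sample ids, and -- when the five Tessier
#' fractions are present -- a sequential-extraction mass balance: the
#' fraction sum must lie within `soil_cd * (1 +/- recovery_tol)`.
#'
#' @param data A data frame with the columns of [cd_schema()].
#' @param schema_mode `"strict"` turns every violation into an error;
#'   `"lenient"` collects them as character warnings attached to the result
#'   as attribute `"validation"`.
#' @param texture_tol Allowed absolute deviation of clay+silt+sand from 100.
#' @param recovery_tol Allowed relative deviation of the Tessier fraction sum
#'   from total soil Cd (0.10 reflects a 95 +/- 5% extraction recovery).
#' @return The validated data frame (invisibly unchanged apart from the
#'   `"validation"` attribute in lenient mode).
#' @export
validate_dataset <- function(data, schema_mode = c("strict", "lenient"),
                             texture_tol = 0.5, recovery_tol = 0.10) {
  schema_mode <- match.arg(schema_mode)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  sch <- cd_schema()
  missing_req <- setdiff(sch$column[sch$required], names(data))
  if (length(missing_req)) {
    stop_cd("schema_error", paste0("missing mandatory column(s): ",
                                   paste(missing_req, collapse = ", ")))
  }
  if (nrow(data) < 1L) stop_cd("schema_error", "dataset has no rows")
  if (anyDuplicated(data$sample_id)) {
    stop_cd("schema_error", "sample_id values are not unique")
  }

  num_cols <- setdiff(intersect(sch$column, names(data)), "sample_id")
  for (cc in num_cols) {
    v <- data[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      if (schema_mode == "strict" && length(bad)) {
        stop_cd("parse_error", sprintf(
          "non-numeric value in column '%s', row %d", cc, bad[1]))
      }
      data[[cc]] <- suppressWarnings(as.numeric(as.character(v)))
      if (length(bad)) note(sprintf(
        "column '%s': %d non-numeric cell(s) set to NA", cc, length(bad)))
    }
  }

  conc <- setdiff(num_cols, c("ph"))
  for (cc in conc) {
    bad <- which(data[[cc]] < 0)
    if (length(bad)) note(sprintf(
      "column '%s': negative concentration in row(s) %s", cc,
      paste(utils::head(bad, 5), collapse = ",")))
  }
  bad_ph <- which(!is.na(data$ph) & (data$ph <= 0 | data$ph >= 14))
  if (length(bad_ph)) note(sprintf(
    "pH outside (0, 14) in row(s) %s", paste(bad_ph, collapse = ",")))

  tex <- data$clay + data$silt + data$sand
  bad_tex <- which(!is.na(tex) & abs(tex - 100) > texture_tol)
  if (length(bad_tex)) note(sprintf(
    "clay+silt+sand differs from 100 by more than %g in row(s) %s",
    texture_tol, paste(utils::head(bad_tex, 5), collapse = ",")))

  have_fr <- .fraction_cols %in% names(data)
  if (any(have_fr) && !all(have_fr)) {
    note(paste0("incomplete Tessier fraction group; missing: ",
                paste(.fraction_cols[!have_fr], collapse = ", ")))
  }
  if (all(have_fr)) {
    fsum <- rowSums(data[.fraction_cols])
    rel <- abs(fsum - data$soil_cd) / data$soil_cd
    bad_fr <- which(!is.na(rel) & rel > recovery_tol)
    if (length(bad_fr)) note(sprintf(
      "Tessier fraction sum outside soil_cd*(1 +/- %g) in row(s) %s",
      recovery_tol, paste(utils::head(bad_fr, 5), collapse = ",")))
  }

  if (length(problems) && schema_mode == "strict") {
    stop_cd("validation_error",
            paste0("dataset failed validation:\n  - ",
                   paste(problems, collapse = "\n  - ")))
  }
  attr(data, "validation") <- problems
  data
}

#' Read a soil-wheat dataset from CSV
#'
#' Reads a UTF-8 CSV with a header row, maps header names onto the canonical
#' schema (case-insensitive, with aliases such as `"Ex-Cd"` for `ex_cd`), and
#' validates the result with [validate_dataset()].
#'
#' @param path Path to the CSV file.
#' @param schema_mode `"strict"` (default) or `"lenient"`; see
#'   [validate_dataset()].
#' @inheritParams validate_dataset
#' @return A validated data frame with attribute `"provenance"` recording the
#'   source file.
#' @export
read_dataset <- function(path, schema_mode = c("strict", "lenient"),
                         texture_tol = 0.5, recovery_tol = 0.10) {
  schema_mode <- match.arg(schema_mode)
  if (!file.exists(path)) stop_cd("io_error", paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  names(raw) <- .normalise_header(names(raw))
  out <- validate_dataset(raw, schema_mode = schema_mode,
                          texture_tol = texture_tol,
                          recovery_tol = recovery_tol)
  attr(out, "provenance") <- paste0("file:", path)
  out
}

#' Bioconcentration factor (BCF)
#'
#' The BCF is the ratio of the Cd concentration in wheat grain to the Cd
#' concentration in the paired topsoil, both in mg/kg dry weight. It is
#' unitless and scale-invariant: rescaling both concentrations by the same
#' positive constant leaves it unchanged.
#'
#' @param grain_cd Grain Cd concentration(s), mg/kg dry wt.
#' @param soil_cd Paired total soil Cd concentration(s), mg/kg dry wt; must
#'   be strictly positive.
#' @return `grain_cd / soil_cd`, vectorised.
#' @export
compute_bcf <- function(grain_cd, soil_cd) {
  if (any(!is.na(soil_cd) & soil_cd == 0)) {
    stop_cd("domain_error", "BCF undefined: soil_cd is zero")
  }
  if (any(!is.na(soil_cd) & soil_cd < 0) || any(!is.na(grain_cd) & grain_cd < 0)) {
    stop_cd("domain_error", "BCF requires non-negative concentrations")
  }
  grain_cd / soil_cd
}

#' Strict base-10 logarithm
#'
#' All logarithms in this package are base 10 (the `Lg`/`log[...]` convention
#' of the soil-plant transfer literature), so fitted coefficients read as
#' effects per tenfold change. Non-positive inputs are a hard error naming
#' the offending sample rather than silently becoming `-Inf`.
#'
#' @param x Positive numeric vector.
#' @param ids Optional sample labels used in the error message.
#' @return `log10(x)`.
#' @export
log10_strict <- function(x, ids = NULL) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste("row", paste(bad, collapse = ", "))
    stop_cd("domain_error",
            paste0("log10 undefined for non-positive value(s) at: ", lab))
  }
  log10(x)
}

#' Add derived columns (BCF, log[BCF], log[OM]) to a dataset
#'
#' @param data A validated soil-wheat data frame.
#' @return The data frame with columns `bcf`, `log_bcf` and `log_om` added.
#' @export
add_derived <- function(data) {
  data$bcf <- compute_bcf(data$grain_cd, data$soil_cd)
  data$log_bcf <- log10_strict(data$bcf, data$sample_id)
  data$log_om <- log10_strict(data$om, data$sample_id)
  data
}

#' Write result tables plus a JSON run manifest
#'
#' Writes one CSV per named table (deterministic column order, full numeric
#' precision so round-trips preserve at least 12 significant digits) and a
#' `manifest.json` recording the tables written, the configuration and seed,
#' and package/R versions. The manifest contains no timestamp, so a rerun
#' with the same inputs is byte-identical.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list describing the run configuration.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_cd("io_error", paste0("cannot create directory: ", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop_cd("io_error", paste0("directory not writable: ", out_dir))
  }
  if (!length(tables)) {
    warn_cd("empty_output", "no tables supplied; writing manifest only")
  }
  files <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) {
      ifelse(is.na(v), NA, format(v, digits = 15, scientific = FALSE,
                                  trim = TRUE))
    })
    utils::write.csv(tab, fp, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    files <- c(files, basename(fp))
  }
  manifest <- list(
    tables = as.list(files),
    config = config,
    seed = seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("cdtransfer"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
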