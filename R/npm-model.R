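#' Load a Nutrient Profiling Model threshold table
#'
#' NPM variants are configuration, not code: a model is a YAML document
#' holding the banded cutpoints for the four "A" components (energy,
#' saturated fat, sugars, sodium/salt), the three "C" components
#' (fruit/vegetables/nuts, fibre, protein), the protein-capping rule and the
#' HFSS cutoffs for foods and drinks. Two models ship with the package:
#' `"NPM2004"`, the 2004/05 Ofcom model (total sugars, sodium), and
#' `"NPM2018"`, a provisional encoding of the 2018 consultation deltas
#' (free sugars, salt, rescaled fibre and energy components).
#'
#' @param name Model identifier. For bundled models one of
#'   [npm_models()]; ignored when `path` points at a single-model file whose
#'   `name` field matches.
#' @param path Optional path to a YAML model file; defaults to the bundled
#'   `models/` directory.
#' @return An object of class `npm_model_spec`: a validated list with
#'   elements `name`, `status`, `sugar_field`, `sodium_field`, `a_bands`,
#'   `c_bands`, `protein_cap` and `cutoffs`.
#' @export
#' @examples
#' spec <- load_model_spec("NPM2004")
#' spec$cutoffs
load_model_spec <- function(name = "NPM2004", path = NULL) {
  if (is.null(path)) {
    path <- system.file("models", paste0(name, ".yaml"), package = "nutrioverlap")
    if (!nzchar(path)) {
      abort(
        c(
          sprintf("Unknown bundled model '%s'.", name),
          sprintf("Bundled models: %s.", paste(npm_models(), collapse = ", "))
        ),
        class = "nutrioverlap_unknown_model"
      )
    }
  }
  if (!file.exists(path)) {
    abort(sprintf("Model file '%s' does not exist.", path),
          class = "nutrioverlap_missing_file")
  }
  raw <- yaml::read_yaml(path)
  if (!identical(raw$name, name)) {
    abort(sprintf("Model file '%s' defines '%s', not '%s'.", path, raw$name, name),
          class = "nutrioverlap_unknown_model")
  }
  validate_model_spec(raw)
}

#' @describeIn load_model_spec Names of the bundled NPM variants.
#' @export
npm_models <- function() {
  files <- list.files(system.file("models", package = "nutrioverlap"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

validate_model_spec <- function(spec) {
  bad <- function(msg) {
    abort(c(sprintf("Invalid NPM model spec '%s'.", spec$name %||% "<unnamed>"), msg),
          class = "nutrioverlap_invalid_model")
  }
  required <- c("name", "sugar_field", "sodium_field", "a_bands", "c_bands",
                "protein_cap", "cutoffs")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) bad(sprintf("missing fields: %s", paste(missing, collapse = ", ")))

  if (!spec$sugar_field %in% c("total_sugars_g", "free_sugars_g")) {
    bad("sugar_field must be 'total_sugars_g' or 'free_sugars_g'")
  }
  if (!spec$sodium_field %in% c("sodium_mg", "salt_g")) {
    bad("sodium_field must be 'sodium_mg' or 'salt_g'")
  }

  check_bands <- function(cuts, label, max_len) {
    cuts <- as.numeric(cuts)
    if (length(cuts) < 1 || length(cuts) > max_len) {
      bad(sprintf("%s: band list length must be in 1..%d", label, max_len))
    }
    if (any(diff(cuts) <= 0)) {
      bad(sprintf("%s: cutpoints must be strictly increasing", label))
    }
    cuts
  }

  a_names <- c("energy_kj", "sat_fat_g", "sugars_g", "sodium")
  if (!setequal(names(spec$a_bands), a_names)) {
    bad(sprintf("a_bands must have exactly: %s", paste(a_names, collapse = ", ")))
  }
  spec$a_bands <- lapply(
    stats::setNames(a_names, a_names),
    function(nm) check_bands(spec$a_bands[[nm]], paste0("a_bands$", nm), 10)
  )

  fvn <- spec$c_bands$fvn_pct
  if (is.null(fvn$cutpoints) || is.null(fvn$points)) {
    bad("c_bands$fvn_pct needs 'cutpoints' and 'points'")
  }
  fvn$cutpoints <- check_bands(fvn$cutpoints, "c_bands$fvn_pct", 5)
  fvn$points <- as.numeric(fvn$points)
  if (length(fvn$points) != length(fvn$cutpoints) || any(diff(fvn$points) <= 0) ||
      any(fvn$points > 5)) {
    bad("c_bands$fvn_pct$points must be strictly increasing, <= 5, one per cutpoint")
  }
  spec$c_bands$fvn_pct <- fvn

  if (length(spec$c_bands$fibre) < 1) bad("c_bands$fibre must list at least one basis")
  if (!all(names(spec$c_bands$fibre) %in% c("NSP", "AOAC"))) {
    bad("fibre bases must be 'NSP' and/or 'AOAC'")
  }
  spec$c_bands$fibre <- lapply(
    stats::setNames(names(spec$c_bands$fibre), names(spec$c_bands$fibre)),
    function(nm) check_bands(spec$c_bands$fibre[[nm]], paste0("c_bands$fibre$", nm), 5)
  )
  spec$c_bands$protein_g <- check_bands(spec$c_bands$protein_g, "c_bands$protein_g", 5)

  pc <- spec$protein_cap
  if (!is.numeric(pc$a_threshold) || !is.numeric(pc$exemption_fvn_points)) {
    bad("protein_cap needs numeric a_threshold and exemption_fvn_points")
  }
  co <- spec$cutoffs
  if (!is.numeric(co$food) || !is.numeric(co$drink) ||
      co$food != round(co$food) || co$drink != round(co$drink)) {
    bad("cutoffs$food and cutoffs$drink must be integers")
  }
  structure(spec, class = "npm_model_spec")
}

#' @export
print.npm_model_spec <- function(x, ...) {
  cat(sprintf("<npm_model_spec> %s (%s)\n", x$name, x$status %||% "unspecified"))
  cat(sprintf("  sugars: %s, sodium basis: %s\n", x$sugar_field, x$sodium_field))
  cat(sprintf("  fibre bases: %s\n", paste(names(x$c_bands$fibre), collapse = ", ")))
  cat(sprintf("  HFSS cutoffs: food >= %d, drink >= %d\n",
              x$cutoffs$food, x$cutoffs$drink))
  invisible(x)
}
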