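# internal helpers shared across modules

# kJ per kcal, used wherever diary energy and per-100 g energy are reconciled
KJ_PER_KCAL <- 4.184

# salt (g) = sodium (mg) * 2.5 / 1000
SODIUM_MG_TO_SALT_G <- 2.5 / 1000

#' Round half away from zero
#'
#' Reported percentages are rounded to one decimal place with halves rounded
#' away from zero (so 50.55 prints as 50.6), the convention used in published
#' diet-survey tables. Base `round()` rounds half to even and would print
#' 50.55 as 50.5.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(50.55, -50.55, 2.25), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# run code with a temporary RNG state; restores (or removes) .Random.seed
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# abort with a bulleted list of row-level problems (line = 1-based data row)
abort_problems <- function(header, problems, class) {
  stopifnot(nrow(problems) > 0)
  shown <- head(problems, 20)
  bullets <- sprintf("line %s: %s", shown$line, shown$message)
  if (nrow(problems) > nrow(shown)) {
    bullets <- c(bullets, sprintf("... and %d more", nrow(problems) - nrow(shown)))
  }
  abort(c(header, bullets), class = class, problems = problems)
}

is_flag_col <- function(x) is.logical(x) && !anyNA(x)
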