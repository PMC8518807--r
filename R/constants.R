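# Ideal-gas constant used throughout (J mol^-1 K^-1).  Concentrations are
# mol L^-1, time is s, activities are ideal (gamma = 1), isothermal.
R_GAS <- 8.314

# Package-wide default seed for every stochastic choice (multistart root
# searches, probe directions, random fixture networks).
DEFAULT_SEED <- 20210805L

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 17-significant-digit decimal formatting: round-trips doubles exactly.
fmt_num <- function(x) {
  vapply(x, function(xi) trimws(formatC(xi, digits = 17, format = "g")),
         character(1))
}
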