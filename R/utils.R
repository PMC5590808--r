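#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the IEC 60559 banker's
#' rounding of base [round()]. Survey reports conventionally round 163.25 to
#' 163.3, so every user-facing rounding step in this package goes through
#' this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(163.25, 1)  # 163.3, where round() gives 163.2
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards against 0.49999999... binary representations
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' The two study islands
#'
#' @return Character vector of the two island names, high-predation first.
#'   This ordering fixes the factor reference level used by every fitter.
#' @export
island_levels <- function() c("Koram", "NomSao")

#' Snail taxa counted on the point transects
#' @return Character vector of species codes.
#' @export
snail_species <- function() c("P_sulcatus", "C_bifasciatus", "M_labio")

#' Prey taxa with size records
#' @return Character vector of taxon codes.
#' @export
prey_taxa <- function() c("oyster", snail_species())

# Derive a reproducible sub-seed for a named random stream. One user-facing
# seed governs every stream; streams are separated by fixed offsets so each
# generation stage is independently reproducible. Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  offsets <- c(
    oyster_tools = 1L, snail_tools = 2L, stone_quadrats = 3L,
    snail_transects = 4L, prey_sizes = 5L, maturation = 6L,
    permutation = 7L, bootstrap = 8L, pipeline = 9L
  )
  if (!stream %in% names(offsets)) stop("unknown random stream: ", stream)
  as.integer((as.numeric(seed) * 10007 + offsets[[stream]]) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument checks -------------------------------------------------

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number", call. = FALSE)
  if (strict && x <= lower) stop(name, " must be > ", lower, call. = FALSE)
  if (!strict && x < lower) stop(name, " must be >= ", lower, call. = FALSE)
  x
}

check_island <- function(island) {
  bad <- setdiff(unique(as.character(island)), island_levels())
  if (length(bad))
    stop("unknown island label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(island_levels(), collapse = " or "), ")",
         call. = FALSE)
  factor(as.character(island), levels = island_levels())
}
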