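#' Trait direction presets and parsing
#'
#' A direction specification says, per trait, whether larger values are
#' favourable (`"benefit"`, synonym `"max"`) or smaller values are
#' (`"cost"`, synonym `"min"`).  It is the researcher's call: for a warm,
#' irrigated barley programme early maturity and short stature are assets,
#' so days to heading (DHE), days to maturity (DMA) and plant height (PLH)
#' are costs, while grain-filling period (GFP), thousand-kernel weight (TKW)
#' and grain yield (YLD) are benefits.  That bundle ships as the
#' `"warm-barley"` preset.
#'
#' @param x a preset name (currently `"warm-barley"`), a named character
#'   vector mapping trait names to `"benefit"`/`"cost"`/`"max"`/`"min"`, or a
#'   path to a config file of `trait=direction` lines (`#` comments allowed).
#' @return named character vector with values `"benefit"` or `"cost"`.
#' @examples
#' siig_directions("warm-barley")
#' siig_directions(c(YLD = "max", DMA = "min"))
#' @export
siig_directions <- function(x = "warm-barley") {
  if (is.character(x) && is.null(names(x)) && length(x) == 1L) {
    preset <- sub("^preset:", "", x)
    if (preset %in% names(.direction_presets)) return(.direction_presets[[preset]])
    if (file.exists(x)) return(parse_direction_file(x))
    stop("unknown direction preset or file: '", x, "' (presets: ",
         paste(names(.direction_presets), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("directions must be a preset name or a named character vector",
         call. = FALSE)
  canonical_directions(x)
}

.direction_presets <- list(
  "warm-barley" = c(DHE = "cost", DMA = "cost", GFP = "benefit",
                    PLH = "cost", TKW = "benefit", YLD = "benefit")
)

canonical_directions <- function(x) {
  map <- c(benefit = "benefit", max = "benefit", high = "benefit",
           cost = "cost", min = "cost", low = "cost")
  val <- map[tolower(x)]
  if (anyNA(val))
    stop("invalid direction '", x[is.na(val)][1L],
         "' (use benefit/cost or max/min)", call. = FALSE)
  names(val) <- names(x)
  val
}

parse_direction_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s*[=:,\t]\\s*")
  if (any(lengths(parts) != 2L))
    stop("malformed direction file line: '",
         lines[which(lengths(parts) != 2L)[1L]], "'", call. = FALSE)
  canonical_directions(stats::setNames(
    vapply(parts, `[`, character(1), 2L),
    vapply(parts, `[`, character(1), 1L)
  ))
}

# Align a direction spec with the matrix traits: error on missing traits,
# warn on extra keys; returns +1 (benefit) / -1 (cost) in trait order.
direction_signs <- function(directions, traits) {
  directions <- siig_directions(directions)
  missing <- setdiff(traits, names(directions))
  if (length(missing))
    stop("no direction given for trait(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(directions), traits)
  if (length(extra))
    warning("direction spec has entries for absent trait(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  ifelse(directions[traits] == "benefit", 1, -1)
}
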