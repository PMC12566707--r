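# Shared validation helpers and constants.

# Expansion stages in gradient order: bamboo-free, low mixture, high
# mixture, monoculture.
.stages <- c("BF", "LM", "HM", "MB")
.layers <- c("tree", "shrub", "herb")

stop_format <- function(msg, ...) {
  abort(msg, class = "phyloRI_format_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "phyloRI_validation_error", ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = "phyloRI_lookup_error", ...)
}

stop_undefined <- function(msg, ...) {
  abort(msg, class = "phyloRI_undefined_metric", ...)
}

check_layer <- function(layer) {
  if (length(layer) != 1L || !layer %in% .layers) {
    stop_validation(sprintf(
      "`layer` must be one of %s, not '%s'",
      paste0("'", .layers, "'", collapse = ", "), paste(layer, collapse = ",")
    ))
  }
  layer
}

#' Expansion stage and layer levels
#'
#' The four invader-expansion stages (bamboo-free, low mixture, high
#' mixture, monoculture) in gradient order, and the three vegetation
#' layers surveyed.
#'
#' @return A character vector of levels.
#' @export
expansion_stages <- function() .stages

#' @rdname expansion_stages
#' @export
survey_layers <- function() .layers

# Deterministic child seed derived from a parent seed and a string key, so
# per-community randomizations do not depend on iteration order. Kept well
# below .Machine$integer.max.
child_seed <- function(seed, key) {
  h <- 0
  for (k in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + k) %% 1000003
  }
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483647L
}
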