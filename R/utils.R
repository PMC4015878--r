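#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-precision rounding that resolves ties upward (half-up), the
#' convention used when formatting percentage metrics. Base `round()` uses
#' banker's rounding, which turns e.g. 90.205 into 90.20 instead of 90.21.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon so decimal literals sitting just below .5 in binary
  # representation (e.g. 1.005 * 100) still resolve upward
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Path to a bundled resource file
#'
#' @param file file name under the package's `extdata` directory.
#' @return absolute path to the installed file.
#' @export
rc_resource <- function(file) {
  path <- system.file("extdata", file, package = "ratechange")
  if (!nzchar(path)) stop("no bundled resource named '", file, "'")
  path
}

#' Load the bundled lexicons, dictionaries and ontologies
#'
#' Convenience loader for the default pipeline resources: the "regulate"
#' and rate-change trigger lexicons, the rate-direction classes, the word
#' normalization dictionary, the yeast gene synonym dictionary, the
#' positive (rate-change) and negative ontologies and the dependency-type
#' generalization map.
#'
#' @return a named list with elements `regulate_lexicon`,
#'   `ratechange_lexicon`, `rate_directions`, `norm_dict`, `gene_dict`,
#'   `ontology_positive`, `ontology_negative`, `dep_type_map`.
#' @export
load_default_resources <- function() {
  list(
    regulate_lexicon   = read_lexicon(rc_resource("regulate_lexicon.txt"), name = "regulate"),
    ratechange_lexicon = read_lexicon(rc_resource("ratechange_lexicon.txt"), name = "ratechange"),
    rate_directions    = read_rate_directions(rc_resource("rate_direction_classes.tsv")),
    norm_dict          = read_norm_dict(rc_resource("norm_dict.tsv")),
    gene_dict          = read_gene_dict(rc_resource("gene_dictionary.tsv")),
    ontology_positive  = read_ontology(rc_resource("ontology_ratechange.json")),
    ontology_negative  = read_ontology(rc_resource("ontology_negative.json")),
    dep_type_map       = read_dep_type_map(rc_resource("dep_type_map.tsv"))
  )
}
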