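#' @useDynLib biomek, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames optim
#' @importFrom utils head tail
NULL

# Fixed value order per dimension.  The default value comes first: it doubles
# as the deterministic tie-break order for argmax prediction.
.MK_SCHEME <- list(
  KT       = c("Other", "Investigation", "Observation", "Analysis", "Fact", "Method"),
  CL       = c("L3", "L2", "L1"),
  Polarity = c("Positive", "Negative"),
  Manner   = c("Neutral", "High", "Low"),
  Source   = c("Current", "Other")
)

#' The five-dimension meta-knowledge annotation scheme
#'
#' Events are annotated along five independent dimensions: Knowledge Type
#' (`KT`: general information content), Certainty Level (`CL`: expressed
#' confidence), `Polarity` (truth value), `Manner` (rate/level/intensity) and
#' `Source` (origin of the knowledge).  Each dimension has a fixed set of
#' values; the first value of each vector is the default, assigned when the
#' sentence carries no explicit evidence for any other value.
#'
#' @return Named list mapping each dimension name to its legal values,
#'   default first.
#' @export
#' @examples
#' mk_scheme()$Polarity
mk_scheme <- function() .MK_SCHEME

#' Default meta-knowledge values
#'
#' @return Named character vector with one default value per dimension
#'   (`Other`, `L3`, `Positive`, `Neutral`, `Current`).
#' @export
mk_defaults <- function() vapply(.MK_SCHEME, `[`, character(1), 1L)

#' Dimension names of the scheme
#' @return Character vector `c("KT","CL","Polarity","Manner","Source")`.
#' @export
mk_dimensions <- function() names(.MK_SCHEME)

#' Construct a meta-knowledge record
#'
#' @param KT,CL,Polarity,Manner,Source dimension values; defaults are the
#'   scheme defaults.
#' @return Named character vector of length 5 with class `mk_record`.
#' @export
mk_record <- function(KT = "Other", CL = "L3", Polarity = "Positive",
                      Manner = "Neutral", Source = "Current") {
  rec <- c(KT = KT, CL = CL, Polarity = Polarity, Manner = Manner, Source = Source)
  for (d in names(rec)) {
    if (!rec[[d]] %in% .MK_SCHEME[[d]]) {
      stop(sprintf("illegal value '%s' for dimension %s", rec[[d]], d))
    }
  }
  class(rec) <- "mk_record"
  rec
}

#' Derive the two hyper-dimensions from a meta-knowledge record
#'
#' The two binary hyper-dimensions are inferred from combinations of the
#' explicitly assigned dimensions: `Hypothesis` from KT and CL, and
#' `NewKnowledge` from KT, Source and CL.  The rule tables are configuration;
#' the defaults are:
#' \itemize{
#'   \item `Hypothesis = "Yes"` iff KT is `Investigation`, or KT is
#'     `Analysis` with CL in `{L1, L2}` (a speculative analysis);
#'   \item `NewKnowledge = "Yes"` iff Source is `Current`, CL is `L3` and KT
#'     is `Observation` or `Analysis` (a confident result of this study).
#' }
#'
#' @param mk an `mk_record` (or named character vector with the five
#'   dimensions).
#' @param rules optional list with function elements `hypothesis(mk)` and
#'   `new_knowledge(mk)`, each returning `TRUE`/`FALSE`, to override the
#'   default rule tables.
#' @return Named character vector `c(NewKnowledge=..., Hypothesis=...)` with
#'   values `"Yes"`/`"No"`.
#' @export
#' @examples
#' derive_hyperdimensions(mk_record(KT = "Investigation"))
derive_hyperdimensions <- function(mk, rules = NULL) {
  stopifnot(all(mk_dimensions() %in% names(mk)))
  hyp_rule <- function(m) {
    m[["KT"]] == "Investigation" ||
      (m[["KT"]] == "Analysis" && m[["CL"]] %in% c("L1", "L2"))
  }
  nk_rule <- function(m) {
    m[["Source"]] == "Current" && m[["CL"]] == "L3" &&
      m[["KT"]] %in% c("Observation", "Analysis")
  }
  if (!is.null(rules$hypothesis)) hyp_rule <- rules$hypothesis
  if (!is.null(rules$new_knowledge)) nk_rule <- rules$new_knowledge
  c(NewKnowledge = if (isTRUE(nk_rule(mk))) "Yes" else "No",
    Hypothesis   = if (isTRUE(hyp_rule(mk))) "Yes" else "No")
}
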