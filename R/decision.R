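# Decision engine: combines geographic, clustering, and niche-test evidence
# into cohesion-species verdicts under explicit rejection rules.
#
# Genetic exchangeability (GE) is rejected iff an allopatric lineage pair
# shows separate molecular clustering, or a parapatric pair shows separate
# clustering AND an asserted barrier to gene flow. Ecological
# interchangeability (EI) is rejected iff the equivalency test rejects
# identity AND every similarity direction used indicates niche divergence.
# Two policies map the verdict pair to a species-status conclusion:
# `conservative_both` (separate species only when both are rejected) and
# `flowchart_either` (either rejection suffices).

#' Assemble the evidence for one lineage pair
#'
#' @param pair character pair of lineage labels.
#' @param geography `"allopatric"`, `"parapatric"`, or `"sympatric"`.
#' @param barrier logical: is an obvious barrier to gene flow asserted?
#'   (always user-asserted expert metadata, never inferred).
#' @param barrier_name free-text barrier description.
#' @param morphology morphology clustering verdict (`"separate"` /
#'   `"overlapping"`), recorded but non-decisive.
#' @param molecular character vector of molecular clustering verdicts, one
#'   per SNP dataset (`"separate"` / `"overlapping"`).
#' @param overlap_d observed Schoener's D.
#' @param equivalency equivalency-test outcome (`"not equivalent"` /
#'   `"not significant"`).
#' @param similarity named list: per background method, a character vector of
#'   per-direction similarity outcomes (`"conservatism"`, `"divergence"`,
#'   `"not significant"`).
#' @param reproductive_isolation user-asserted flag, only consulted for
#'   sympatric pairs.
#' @return a `lineage_pair_assessment`.
#' @export
lineage_pair_assessment <- function(pair, geography, barrier = FALSE,
                                    barrier_name = NA_character_,
                                    morphology = NA_character_,
                                    molecular = character(),
                                    overlap_d = NA_real_,
                                    equivalency = NA_character_,
                                    similarity = list(),
                                    reproductive_isolation = FALSE) {
  geography <- match.arg(geography, c("allopatric", "parapatric", "sympatric"))
  structure(list(pair = pair, geography = geography, barrier = barrier,
                 barrier_name = barrier_name, morphology = morphology,
                 molecular = molecular, overlap_d = overlap_d,
                 equivalency = equivalency, similarity = similarity,
                 reproductive_isolation = reproductive_isolation),
            class = "lineage_pair_assessment")
}

# majority aggregation of molecular clustering verdicts; ties fail to the
# non-rejecting side ("overlapping")
aggregate_molecular <- function(verdicts) {
  verdicts <- verdicts[!is.na(verdicts)]
  if (!length(verdicts)) stop("no molecular clustering verdict available")
  if (sum(verdicts == "separate") > length(verdicts) / 2) "separate"
  else "overlapping"
}

#' Assess genetic exchangeability for a lineage pair
#'
#' @param a a [lineage_pair_assessment] with geography and at least one
#'   molecular clustering verdict.
#' @return `"rejected"` or `"not rejected"`, with an `evidence` attribute
#'   stating which rule fired.
#' @export
assess_ge <- function(a) {
  if (is.null(a$geography) || is.na(a$geography)) stop("geography is required")
  mol <- aggregate_molecular(a$molecular)
  rejected <- switch(a$geography,
    allopatric = mol == "separate",
    parapatric = mol == "separate" && isTRUE(a$barrier),
    sympatric = mol == "separate" && isTRUE(a$reproductive_isolation))
  evidence <- sprintf(
    "geography=%s, molecular=%s (majority of %d dataset(s)), barrier=%s%s",
    a$geography, mol, length(a$molecular), isTRUE(a$barrier),
    if (!is.na(a$barrier_name)) paste0(" (", a$barrier_name, ")") else "")
  structure(if (rejected) "rejected" else "not rejected", evidence = evidence)
}

#' Assess ecological interchangeability for a lineage pair
#'
#' @param a a [lineage_pair_assessment] with an equivalency outcome and
#'   similarity outcomes for `background_method`.
#' @param background_method which background-region method's similarity
#'   outcomes decide the verdict (default `"thresh75"`).
#' @return `"rejected"` or `"not rejected"`, with an `evidence` attribute.
#' @export
assess_ei <- function(a, background_method = "thresh75") {
  missing <- character()
  if (is.na(a$equivalency %||% NA)) missing <- c(missing, "equivalency outcome")
  sims <- a$similarity[[background_method]]
  if (is.null(sims) || !length(sims))
    missing <- c(missing, sprintf("similarity outcomes for method '%s'",
                                  background_method))
  if (length(missing))
    stop("missing: ", paste(missing, collapse = "; "))
  rejected <- a$equivalency == "not equivalent" && all(sims == "divergence")
  evidence <- sprintf("equivalency=%s; similarity[%s]=%s", a$equivalency,
                      background_method, paste(sims, collapse = ","))
  structure(if (rejected) "rejected" else "not rejected", evidence = evidence)
}

#' Combine GE and EI verdicts into a species-status conclusion
#'
#' @param ge,ei verdicts (`"rejected"` / `"not rejected"`), e.g. from
#'   [assess_ge] and [assess_ei].
#' @param policy `"conservative_both"` — separate cohesion species only when
#'   both exchangeability mechanisms are rejected; `"flowchart_either"` —
#'   either rejection suffices.
#' @return a `cohesion_decision` with the conclusion (`"separate species"` /
#'   `"single species"`), the verdicts, the policy, and an evidence trail.
#' @export
delimit <- function(ge, ei, policy = c("conservative_both",
                                       "flowchart_either")) {
  policy <- match.arg(policy)
  stopifnot(ge %in% c("rejected", "not rejected"),
            ei %in% c("rejected", "not rejected"))
  separate <- switch(policy,
    conservative_both = ge == "rejected" && ei == "rejected",
    flowchart_either = ge == "rejected" || ei == "rejected")
  trail <- c(sprintf("GE %s%s", ge,
                     if (!is.null(attr(ge, "evidence")))
                       paste0(" [", attr(ge, "evidence"), "]") else ""),
             sprintf("EI %s%s", ei,
                     if (!is.null(attr(ei, "evidence")))
                       paste0(" [", attr(ei, "evidence"), "]") else ""),
             sprintf("policy %s -> %s", policy,
                     if (separate) "separate species" else "single species"))
  structure(list(ge = as.character(ge), ei = as.character(ei),
                 policy = policy,
                 conclusion = if (separate) "separate species"
                              else "single species",
                 evidence = trail),
            class = "cohesion_decision")
}

#' @export
print.cohesion_decision <- function(x, ...) {
  cat(sprintf("<cohesion_decision> %s (GE %s, EI %s, policy %s)\n",
              x$conclusion, x$ge, x$ei, x$policy))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Build the summary delimitation table
#'
#' One row per lineage-pair assessment, mirroring the usual presentation of
#' cohesion delimitation studies: geography/barrier, morphology and molecular
#' clustering with the GE conclusion, then sample sizes, D, the two niche
#' tests and the EI conclusion, and the species-status conclusion under the
#' chosen policy.
#'
#' @param assessments list of [lineage_pair_assessment]s (may be empty).
#' @param policy delimitation policy passed to [delimit].
#' @param background_method similarity method passed to [assess_ei].
#' @param n_occ optional list of `c(n_a, n_b)` per assessment.
#' @return a data frame with one row per assessment.
#' @export
build_table2 <- function(assessments, policy = "conservative_both",
                         background_method = "thresh75", n_occ = NULL) {
  cols <- c("comparison", "geography", "barrier", "morphology", "molecular",
            "ge", "n_a", "n_b", "overlap_d", "equivalency", "similarity",
            "ei", "conclusion")
  if (!length(assessments)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    out$n_a <- integer(0); out$n_b <- integer(0); out$overlap_d <- numeric(0)
    return(out)
  }
  rows <- lapply(seq_along(assessments), function(i) {
    a <- assessments[[i]]
    ge <- assess_ge(a)
    ei <- assess_ei(a, background_method)
    dec <- delimit(ge, ei, policy)
    nn <- if (!is.null(n_occ)) n_occ[[i]] else c(NA_integer_, NA_integer_)
    data.frame(
      comparison = paste(a$pair, collapse = " to "),
      geography = a$geography,
      barrier = if (!isTRUE(a$barrier)) "none"
                else if (is.na(a$barrier_name)) "present" else a$barrier_name,
      morphology = a$morphology %||% NA_character_,
      molecular = aggregate_molecular(a$molecular),
      ge = as.character(ge), n_a = nn[1], n_b = nn[2],
      overlap_d = a$overlap_d,
      equivalency = a$equivalency,
      similarity = paste(a$similarity[[background_method]], collapse = ","),
      ei = as.character(ei), conclusion = dec$conclusion,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
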