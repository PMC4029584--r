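#' Allelic states of a single haplotype
#'
#' Each haplotype at a SNP locus carries one of six allelic states: the A or
#' B allele at normal single copy (\code{"A"}, \code{"B"}), amplified
#' (\code{"A+"}, \code{"B+"}) or deleted (\code{"A-"}, \code{"B-"}).
#'
#' @return Character vector of the six state labels, in canonical order
#'   \code{A-, A, A+, B-, B, B+}.
#' @export
allelic_states <- function() {
  c("A-", "A", "A+", "B-", "B", "B+")
}

#' @rdname allelic_states
#' @param state character vector of allelic state labels.
#' @return \code{state_allele}: the allele letter ("A"/"B");
#'   \code{state_class}: "loss", "normal" or "gain";
#'   \code{state_copies}: integer copy count (0, 1 or 2) contributed by the
#'   haplotype.
#' @export
state_allele <- function(state) {
  substr(state, 1L, 1L)
}

#' @rdname allelic_states
#' @export
state_class <- function(state) {
  suffix <- substring(state, 2L)
  out <- ifelse(suffix == "+", "gain", ifelse(suffix == "-", "loss", "normal"))
  out[!state %in% allelic_states()] <- NA_character_
  out
}

#' @rdname allelic_states
#' @export
state_copies <- function(state) {
  cls <- state_class(state)
  ifelse(cls == "gain", 2L, ifelse(cls == "loss", 0L, 1L))
}

#' Allowed transitions between allelic states on one haplotype
#'
#' A normal state can transit to any of the six states; a gain state can only
#' transit to a gain or a normal state; a loss state only to a loss or a
#' normal state. Adjacent gain and loss segments are thereby forbidden, which
#' leaves 28 allowed ordered transitions out of the 6 x 6 = 36 pairs.
#'
#' @return A 6 x 6 logical matrix, rows = from-state, cols = to-state, in
#'   the order of [allelic_states()].
#' @export
allowed_transitions <- function() {
  st <- allelic_states()
  from_cls <- state_class(st)
  to_cls <- state_class(st)
  ok <- outer(from_cls, to_cls, function(f, t) {
    !((f == "gain" & t == "loss") | (f == "loss" & t == "gain"))
  })
  dimnames(ok) <- list(from = st, to = st)
  ok
}

#' Ordered genotype states of a diploid
#'
#' The diploid hidden state at a locus is the ordered pair of the two
#' haplotypes' allelic states, 36 in total. Order is meaningful: the first
#' element tracks haplotype 1 across loci.
#'
#' @return Character vector of 36 labels \code{"<h1>|<h2>"}, ordered by
#'   (haplotype-1 state, haplotype-2 state) in the canonical state order.
#' @export
genotype_states <- function() {
  st <- allelic_states()
  as.vector(t(outer(st, st, function(a, b) paste(a, b, sep = "|"))))
}

#' Split genotype state labels into the two haplotype states
#'
#' @param gs character vector of genotype state labels (\code{"A|B"} etc.).
#' @return A 2-column character matrix (h1, h2).
#' @export
genotype_state_pair <- function(gs) {
  parts <- strsplit(gs, "|", fixed = TRUE)
  m <- do.call(rbind, parts)
  colnames(m) <- c("h1", "h2")
  m
}

# Table of genotypic-state membership for the eleven emission models.
# Each of the 36 ordered states maps to exactly one model M0..M10; states in
# the same model share an expected (A,B) signal position.
.model_members <- list(
  M0  = c("A+|A+", "A+|A", "A|A+"),
  M1  = c("A|A", "A-|A+", "A+|A-", "A+|B-", "B-|A+"),
  M2  = c("A+|B", "B|A+"),
  M3  = c("A+|B+", "B+|A+"),
  M4  = c("A|B-", "B-|A", "A|A-", "A-|A"),
  M5  = c("A|B", "B|A"),
  M6  = c("A|B+", "B+|A"),
  M7  = c("B-|B-", "A-|A-", "A-|B-", "B-|A-"),
  M8  = c("A-|B", "B|A-", "B|B-", "B-|B"),
  M9  = c("B|B", "B-|B+", "B+|B-", "B+|A-", "A-|B+"),
  M10 = c("B+|B+", "B+|B", "B|B+")
)

#' Emission-model membership of the 36 genotype states
#'
#' Genotypic states whose expected allele signals coincide are grouped into
#' eleven emission models M0..M10 (e.g. \code{A|A} and \code{A-|A+} both
#' present two A copies and no B, hence share model M1). The grouping is a
#' partition: every ordered state belongs to exactly one model.
#'
#' @param gs optional character vector of genotype state labels; default all
#'   36 states.
#' @return Named character vector mapping each state to its model id.
#' @export
genotype_state_model <- function(gs = genotype_states()) {
  map <- rep(names(.model_members), lengths(.model_members))
  names(map) <- unlist(.model_members, use.names = FALSE)
  out <- map[gs]
  if (anyNA(out)) {
    stop("genotype state(s) not covered by any emission model: ",
         paste(gs[is.na(out)], collapse = ", "))
  }
  names(out) <- gs
  out
}

#' @rdname genotype_state_model
#' @return \code{model_ids}: the eleven model identifiers in order.
#' @export
model_ids <- function() {
  names(.model_members)
}

#' @rdname genotype_state_model
#' @param model model id, e.g. \code{"M5"}.
#' @return \code{model_member_states}: character vector of member states.
#' @export
model_member_states <- function(model) {
  m <- .model_members[[model]]
  if (is.null(m)) stop("unknown emission model: ", model)
  m
}
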