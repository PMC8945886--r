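#' Assign score-plane quadrants and predict combination sensitivity
#'
#' Places every sample in the plane spanned by the 18-gene RAS-activation
#' score (x axis) and the 13-gene MEKi-resistance score (y axis) and labels
#' its quadrant. "Positive" is strict inequality against the threshold, so a
#' score lying exactly on a boundary is non-positive: a sample with an
#' 18-gene score of exactly 0.00 falls left of the RUQ. Samples in the right
#' upper quadrant — both scores positive — are predicted sensitive to the
#' MEKi + SRCi combination; the prediction is binary, the quadrant rule
#' defines no confidence measure.
#'
#' @param scores A [score_table()]. Standardized scores are used when
#'   present (zero thresholds then sit at the per-signature median),
#'   otherwise scores are taken as supplied.
#' @param sig18,sig13 Names of the two signature columns spanning the plane.
#' @param threshold18,threshold13 Quadrant boundaries, default 0.
#' @param use Which score slot to read: `"auto"` (standardized if present),
#'   `"standardized"` or `"raw"`.
#' @return A data.frame with columns `sample_id`, `score18`, `score13`,
#'   `quadrant` (factor RUQ/LUQ/RLQ/LLQ) and `combo_sensitive_predicted`.
#' @export
assign_quadrants <- function(scores, sig18 = "RAS18", sig13 = "MEKR13",
                             threshold18 = 0, threshold13 = 0,
                             use = c("auto", "standardized", "raw")) {
  stopifnot(inherits(scores, "score_table"))
  use <- match.arg(use)
  mat <- switch(use,
    auto = scores$standardized %||% scores$raw,
    standardized = scores$standardized %||%
      stop("score table has no standardized scores", call. = FALSE),
    raw = scores$raw
  )
  for (sig in c(sig18, sig13)) {
    if (!sig %in% colnames(mat)) {
      stop("signature '", sig, "' not present in score table", call. = FALSE)
    }
  }
  s18 <- mat[, sig18]
  s13 <- mat[, sig13]
  quadrant <- ifelse(s18 > threshold18,
                     ifelse(s13 > threshold13, "RUQ", "RLQ"),
                     ifelse(s13 > threshold13, "LUQ", "LLQ"))
  data.frame(
    sample_id = rownames(mat) %||% character(0),
    score18 = unname(s18),
    score13 = unname(s13),
    quadrant = factor(quadrant, levels = QUADRANT_LEVELS),
    combo_sensitive_predicted = quadrant == "RUQ",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Tabulate CMS class against quadrant
#'
#' @param calls Output of [assign_quadrants()].
#' @param annotations Annotation data.frame as from [read_annotations()];
#'   every sample in `calls` must be annotated.
#' @return An integer matrix of counts, rows CMS1..CMS4 and UNCLASSIFIED,
#'   columns RUQ/LUQ/RLQ/LLQ; row sums equal class sizes among the called
#'   samples.
#' @export
quadrant_summary <- function(calls, annotations) {
  missing <- setdiff(calls$sample_id, annotations$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) without annotation: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cms <- annotations$cms_class[match(calls$sample_id, annotations$sample_id)]
  counts <- table(
    cms_class = factor(cms, levels = CMS_LEVELS),
    quadrant = factor(calls$quadrant, levels = QUADRANT_LEVELS)
  )
  mat <- matrix(as.integer(counts), nrow = length(CMS_LEVELS),
                dimnames = list(CMS_LEVELS, QUADRANT_LEVELS))
  mat
}
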