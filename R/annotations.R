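#' Read a sample-annotation table
#'
#' Expects a delimited file with a header row containing at least `sample_id`
#' and `cms_class`; `msi_status` and `mutation` are carried through when
#' present. CMS labels outside CMS1-CMS4 (any capitalisation of those four is
#' accepted) are mapped to `UNCLASSIFIED` with a warning, so that cohorts
#' with unclassifiable samples still load.
#'
#' @param path Path to a CSV/TSV annotation file.
#' @param delimiter Optional field separator; defaults by file extension.
#' @return A data.frame with columns `sample_id`, `cms_class` (factor with
#'   levels CMS1..CMS4, UNCLASSIFIED), `msi_status`, `mutation`.
#' @export
read_annotations <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delimiter <- delimiter %||% delim_from_path(path)
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  required <- c("sample_id", "cms_class")
  missing <- setdiff(required, colnames(tab))
  if (length(missing) > 0L) {
    stop("annotation file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as_sample_annotations(
    sample_id = as.character(tab$sample_id),
    cms_class = as.character(tab$cms_class),
    msi_status = if ("msi_status" %in% colnames(tab)) as.character(tab$msi_status) else NA_character_,
    mutation = if ("mutation" %in% colnames(tab)) as.character(tab$mutation) else NA_character_
  )
}

#' Build a validated sample-annotation table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param cms_class Character vector of CMS labels (unknown labels become
#'   `UNCLASSIFIED` with a warning).
#' @param msi_status,mutation Optional per-sample annotation, recycled if
#'   scalar.
#' @return A data.frame as in [read_annotations()].
#' @export
as_sample_annotations <- function(sample_id, cms_class,
                                  msi_status = NA_character_,
                                  mutation = NA_character_) {
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  norm <- toupper(trimws(cms_class))
  unknown <- !(norm %in% CMS_LEVELS)
  if (any(unknown)) {
    warning("unrecognised CMS label(s) mapped to UNCLASSIFIED: ",
            paste(unique(cms_class[unknown]), collapse = ", "), call. = FALSE)
    norm[unknown] <- "UNCLASSIFIED"
  }
  data.frame(
    sample_id = as.character(sample_id),
    cms_class = factor(norm, levels = CMS_LEVELS),
    msi_status = rep_len(msi_status, length(sample_id)),
    mutation = rep_len(mutation, length(sample_id)),
    stringsAsFactors = FALSE
  )
}

#' Load the packaged 16-cell-line worked example
#'
#' Sixteen colorectal cancer cell lines with their published molecular
#' annotation (MSI status, driver mutation, CMS class) and three published,
#' already-standardized signature scores: the 18-gene RAS-pathway activation
#' score, the 13-gene MEK-inhibitor resistance score, and the SRC activation
#' score. These are the values the quadrant rule is demonstrated on; they are
#' consumed as supplied and are not regenerated from expression data.
#'
#' @return A list with `annotations` (data.frame as in [read_annotations()])
#'   and `scores` (a [score_table()] whose raw slot holds the published
#'   scores under signature names `RAS18`, `MEKR13`, `SRC61`).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_scores.csv", package = "sigquad",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ann <- as_sample_annotations(tab$sample_id, tab$cms_class,
                               tab$msi_status, tab$mutation)
  raw <- as.matrix(tab[, c("score_18gene", "score_13gene", "score_src")])
  dimnames(raw) <- list(tab$sample_id, c("RAS18", "MEKR13", "SRC61"))
  list(annotations = ann, scores = score_table(raw))
}
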