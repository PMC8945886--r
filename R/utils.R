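`%||%` <- function(x, y) if (is.null(x)) y else x

# recognised consensus molecular subtype labels; anything else is mapped to
# UNCLASSIFIED at parse time
CMS_LEVELS <- c("CMS1", "CMS2", "CMS3", "CMS4", "UNCLASSIFIED")

QUADRANT_LEVELS <- c("RUQ", "LUQ", "RLQ", "LLQ")

SIGNATURE_ROLES <- c("sig18", "sig13", "src")

delim_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}
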