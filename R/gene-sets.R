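#' Construct a gene set
#'
#' A signature is a named set of up-member gene ids and an optional set of
#' down-members. Both scorers in the package treat a signed set as the
#' up-component score minus the down-component score, which degrades to
#' up-only scoring when `down` is empty.
#'
#' @param name Signature name.
#' @param up Character vector of up-member gene ids (non-empty).
#' @param down Character vector of down-member gene ids; may be empty.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, up, down = character(0)) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(name) != 1L || !nzchar(name)) {
    stop("gene set name must be a single non-empty string", call. = FALSE)
  }
  if (length(up) == 0L) {
    stop("gene set '", name, "' has no up-member genes", call. = FALSE)
  }
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("gene set '", name, "' lists gene(s) as both up and down: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, up = up, down = down), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name description member...`. GMT has no native direction field, so signed
#' signatures are encoded as paired lines `<name>_UP` and `<name>_DN`, merged
#' here into a single [gene_set()]; a bare line (no suffix, or `_UP` with no
#' matching `_DN`) is an up-only set. A `_DN` line without an `_UP` partner is
#' rejected, since a set must have up-members.
#'
#' @param path Path to a GMT file.
#' @return Named list of `gene_set` objects, one per logical signature.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file ", path, " is empty", call. = FALSE)

  raw_names <- character(0)
  raw_members <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)), call. = FALSE)
    }
    if (fields[1L] %in% raw_names) {
      stop("duplicate gene set name in ", path, ": ", fields[1L], call. = FALSE)
    }
    raw_names <- c(raw_names, fields[1L])
    raw_members[[fields[1L]]] <- fields[-(1:2)]
  }

  base_of <- sub("_(UP|DN)$", "", raw_names)
  sets <- list()
  for (base in unique(base_of)) {
    members_up <- raw_members[[paste0(base, "_UP")]]
    members_dn <- raw_members[[paste0(base, "_DN")]]
    if (is.null(members_up) && is.null(members_dn)) {
      # bare, unsigned line
      sets[[base]] <- gene_set(base, up = raw_members[[base]])
    } else {
      if (is.null(members_up)) {
        stop("gene set '", base, "' has a _DN line but no _UP line", call. = FALSE)
      }
      sets[[base]] <- gene_set(base, up = members_up,
                               down = members_dn %||% character(0))
    }
  }
  if (anyDuplicated(names(sets))) {
    dup <- unique(names(sets)[duplicated(names(sets))])
    stop("duplicate merged gene set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' Signed sets are written as `<name>_UP`/`<name>_DN` line pairs, the
#' encoding [read_gmt()] merges back.
#'
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @param description Description field written on every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- unlist(lapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    if (length(s$down) == 0L) {
      paste(c(s$name, description, s$up), collapse = "\t")
    } else {
      c(paste(c(paste0(s$name, "_UP"), description, s$up), collapse = "\t"),
        paste(c(paste0(s$name, "_DN"), description, s$down), collapse = "\t"))
    }
  }))
  writeLines(lines, path)
  invisible(path)
}
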