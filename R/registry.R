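#' Disease registry ingestion
#'
#' Reads a disease list into a registry data frame. Diseases are identified
#' by CURIE-style identifiers (`prefix:digits`, canonically a MONDO id such
#' as `MONDO:0007803`), with a human-readable label and optional synonyms.
#' Three dialects are supported:
#'
#' * `tsv` — `id<TAB>label<TAB>pipe-separated-synonyms` (third column
#'   optional), no header;
#' * `json` — an array of objects with keys `id`, `label`, and optionally
#'   `synonyms`;
#' * `obo` — a minimal OBO subset: `[Term]` stanzas with `id:`, `name:`,
#'   and `synonym: "..."` tags only.
#'
#' Identifiers must match `^[A-Za-z]+:\d+$` and be unique. Non-MONDO
#' prefixes are accepted with a warning, since the scoring method itself is
#' ontology-agnostic.
#'
#' @param path Path to the registry file.
#' @param format One of `"tsv"`, `"json"`, `"obo"`. Default guesses from
#'   the file extension.
#' @return A `disease_registry` data frame with columns `id`, `label`, and
#'   list-column `synonyms`, preserving input order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("MONDO:0007803\tmultiple system atrophy", f)
#' read_disease_registry(f)
#' @export
read_disease_registry <- function(path, format = c("auto", "tsv", "json", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_umni("registry file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      json = "json", obo = "obo", "tsv"
    )
  }
  reg <- switch(format,
    tsv = read_registry_tsv(path),
    json = read_registry_json(path),
    obo = read_registry_obo(path)
  )
  validate_registry(reg)
}

read_registry_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_registry())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
  labels <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[[2L]]) else "", character(1))
  syns <- lapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(trimws(p[[3L]]))) {
      trimws(strsplit(p[[3L]], "|", fixed = TRUE)[[1L]])
    } else {
      character(0)
    }
  })
  make_registry(ids, labels, syns, line = seq_along(lines))
}

read_registry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(obj)) return(empty_registry())
  ids <- vapply(obj, function(r) as.character(r$id %||% ""), character(1))
  labels <- vapply(obj, function(r) as.character(r$label %||% ""), character(1))
  syns <- lapply(obj, function(r) as.character(unlist(r$synonyms %||% list())))
  make_registry(ids, labels, syns, line = seq_along(obj))
}

read_registry_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  in_term <- FALSE
  ids <- character(0); labels <- character(0); syns <- list(); at <- integer(0)
  cur_id <- NA_character_; cur_name <- NA_character_; cur_syn <- character(0); cur_line <- NA_integer_
  flush <- function() {
    if (!is.na(cur_id)) {
      ids <<- c(ids, cur_id)
      labels <<- c(labels, cur_name %||% "")
      syns[[length(syns) + 1L]] <<- cur_syn
      at <<- c(at, cur_line)
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NA_character_; cur_name <- NA_character_; cur_syn <- character(0); cur_line <- i
    } else if (grepl("^\\[", ln)) {
      flush()
      in_term <- FALSE
      cur_id <- NA_character_
    } else if (in_term) {
      if (grepl("^id:", ln)) {
        cur_id <- trimws(sub("^id:", "", ln))
        cur_line <- i
      } else if (grepl("^name:", ln)) {
        cur_name <- trimws(sub("^name:", "", ln))
      } else if (grepl("^synonym:", ln)) {
        m <- regmatches(ln, regexec("^synonym:\\s*\"([^\"]*)\"", ln))[[1L]]
        if (length(m) == 2L) cur_syn <- c(cur_syn, m[[2L]])
      }
    }
  }
  flush()
  if (!length(ids)) return(empty_registry())
  make_registry(ids, labels, syns, line = at)
}

empty_registry <- function() {
  out <- data.frame(id = character(0), label = character(0), stringsAsFactors = FALSE)
  out$synonyms <- list()
  class(out) <- c("disease_registry", "data.frame")
  out
}

make_registry <- function(ids, labels, synonyms, line = NULL) {
  out <- data.frame(id = ids, label = labels, stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  if (!is.null(line)) attr(out, "source_line") <- line
  class(out) <- c("disease_registry", "data.frame")
  out
}

#' Validate a disease registry
#'
#' Enforces the registry invariants: every id matches the CURIE pattern
#' `^[A-Za-z]+:\d+$`, ids are unique, and labels are non-empty after
#' whitespace trimming. Malformed records are reported with their source
#' line when known. Non-MONDO prefixes only warn.
#'
#' @param reg A registry data frame as returned by [read_disease_registry()].
#' @return `reg` (with trimmed labels), invisibly usable downstream.
#' @export
validate_registry <- function(reg) {
  line <- attr(reg, "source_line") %||% seq_len(nrow(reg))
  if (!nrow(reg)) return(reg)
  bad <- !grepl("^[A-Za-z]+:[0-9]+$", reg$id)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_umni(
      "malformed CURIE '", reg$id[i], "' (line ", line[i], "); ",
      sum(bad), " malformed id(s) in total"
    )
  }
  dup <- duplicated(reg$id)
  if (any(dup)) {
    stop_umni("duplicate disease id: ", paste(unique(reg$id[dup]), collapse = ", "))
  }
  reg$label <- trimws(reg$label)
  if (any(!nzchar(reg$label))) {
    i <- which(!nzchar(reg$label))[1L]
    stop_umni("empty label for ", reg$id[i], " (line ", line[i], ")")
  }
  prefix <- sub(":.*$", "", reg$id)
  if (any(prefix != "MONDO")) {
    warn_umni(
      "non-MONDO prefix(es) in registry: ",
      paste(unique(prefix[prefix != "MONDO"]), collapse = ", ")
    )
  }
  reg
}

#' Write a disease registry
#'
#' `write_registry_tsv()` writes the `id<TAB>label<TAB>pipe-separated
#' synonyms` dialect that [read_disease_registry()] reads back exactly;
#' `write_registry_json()` writes the JSON array dialect.
#'
#' @param reg Registry data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_tsv <- function(reg, path) {
  syn <- vapply(reg$synonyms, paste, character(1), collapse = "|")
  writeLines(paste(reg$id, reg$label, syn, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_registry_tsv
#' @export
write_registry_json <- function(reg, path) {
  recs <- lapply(seq_len(nrow(reg)), function(i) {
    list(
      id = reg$id[i], label = reg$label[i],
      synonyms = as.list(reg$synonyms[[i]])
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}
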