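# E.C.-number handling: POI list parsing, descriptor mapping tables and
# the translation into non-redundant GO-term (profile) and PROSITE-ID
# (pattern) filter lists.

EC_CONCRETE_RE <- "^([1-7])\\.([0-9]+)\\.([0-9]+)\\.(n?[0-9]+)$"
EC_WILDCARD_RE <- "^([1-7])\\.([0-9]+)\\.([0-9]+)\\.\\*$"
GO_ID_RE <- "^GO:[0-9]{7}$"
PS_ID_RE <- "^PS[0-9]{5}$"

#' Parse a protein-of-interest E.C. number list
#'
#' One E.C. number per non-blank line; `#` starts a comment; an optional
#' second tab-separated column gives the POI group label. The first three
#' fields must be concrete integers (class 1-7 in field one); only the
#' fourth field may be the wildcard `*`. Preliminary-style serials
#' (`n` + digits, as in the ENZYME release) are accepted as concrete.
#'
#' @param x File path or character vector of lines.
#' @return Data frame with columns `ec` (canonical token), `group` (label
#'   or `NA`), `line` (input line number), preserving input order and
#'   duplicates.
#' @examples
#' parse_ec_list(c("1.1.1.*", "1.3.1.26\tDHPR"))
#' @export
parse_ec_list <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  ec <- character(length(keep)); grp <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(trimws(lines[ln]), "\t", fixed = TRUE)[[1]]
    tok <- trimws(parts[1])
    grp[i] <- if (length(parts) > 1L && nzchar(trimws(parts[2])))
      trimws(parts[2]) else NA_character_
    if (!grepl(EC_CONCRETE_RE, tok) && !grepl(EC_WILDCARD_RE, tok)) {
      nf <- length(strsplit(tok, ".", fixed = TRUE)[[1]])
      hint <- if (nf != 4L) "wrong field count"
        else if (grepl("\\*", sub("\\.[^.]*$", "", tok)))
          "wildcard allowed only in the fourth field"
        else "fields 1-3 must be integers (class 1-7 first)"
      stop("malformed E.C. number ", sQuote(tok), " on line ", ln, ": ", hint)
    }
    ec[i] <- tok
  }
  data.frame(ec = ec, group = grp, line = keep, stringsAsFactors = FALSE)
}

is_ec_wildcard <- function(ec) grepl(EC_WILDCARD_RE, ec)

ec_prefix <- function(ec) sub("\\.[^.]*$", "", ec)

#' Read an ENZYME-release-style flat file
#'
#' Minimal parser for the public `ID`/`DE` flat-file dialect: `ID` lines
#' carry the E.C. number, `DE` lines the description, `//` terminates an
#' entry. Status is derived from the conventions of that dialect:
#' a serial field with an `n` prefix marks a *preliminary* entry; a
#' description starting with "Transferred entry" or "Deleted entry" marks
#' *transferred* / *deleted*; everything else is *active*.
#'
#' @param path File path or character vector of lines.
#' @return Data frame with columns `ec`, `status`
#'   (active/preliminary/transferred/deleted) and `de`.
#' @export
read_enzyme_dat <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  ecs <- character(); des <- character()
  cur_ec <- NA_character_; cur_de <- ""
  for (ln in lines) {
    tag <- substring(ln, 1L, 2L)
    body <- sub("^..[[:space:]]+", "", ln)
    if (tag == "//") {
      if (!is.na(cur_ec)) { ecs <- c(ecs, cur_ec); des <- c(des, cur_de) }
      cur_ec <- NA_character_; cur_de <- ""
    } else if (tag == "ID") {
      cur_ec <- trimws(body)
    } else if (tag == "DE") {
      cur_de <- paste0(cur_de, if (nzchar(cur_de)) " ", body)
    }
  }
  if (!is.na(cur_ec)) { ecs <- c(ecs, cur_ec); des <- c(des, cur_de) }
  status <- rep("active", length(ecs))
  status[grepl("^[0-9.]+\\.n[0-9]+$", ecs)] <- "preliminary"
  status[startsWith(des, "Transferred entry")] <- "transferred"
  status[startsWith(des, "Deleted entry")] <- "deleted"
  data.frame(ec = ecs, status = status, de = des, stringsAsFactors = FALSE)
}

#' Read an ec2go-style mapping file
#'
#' Lines of the public dialect `EC:1.1.1.1 > GO:some name ; GO:0004022`;
#' `!` comment lines are skipped.
#'
#' @param path File path or character vector of lines.
#' @return Data frame with columns `ec` and `go`.
#' @export
read_ec2go <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^EC:([0-9n.*]+)[[:space:]]*>.*;[[:space:]]*(GO:[0-9]{7})[[:space:]]*$", lines))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad))
    stop("cannot parse ec2go line ", bad[1], ": ", sQuote(lines[bad[1]]))
  data.frame(ec = vapply(m, `[[`, "", 2L), go = vapply(m, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Assemble a descriptor mapping
#'
#' Combines an enzyme status table, an EC-to-GO table and an EC-to-PROSITE
#' table into the lookup object used by [expand_and_filter()] and
#' [translate_descriptors()].
#'
#' @param enzyme Data frame from [read_enzyme_dat()] (columns `ec`,
#'   `status`).
#' @param ec2go Data frame with columns `ec`, `go` ([read_ec2go()]).
#' @param ec2prosite Data frame with columns `ec`, `ps`; conveniently built
#'   from [read_prosite_dat()] output via [prosite_ec_links()].
#' @param low_specificity Character vector of PROSITE IDs excluded from
#'   translated pattern lists for low specificity.
#' @return Object of class `descriptor_mapping` with members `ec_status`
#'   (named character), `ec_to_go`, `ec_to_prosite` (named lists of
#'   character vectors) and `low_specificity`.
#' @export
descriptor_mapping <- function(enzyme, ec2go = NULL, ec2prosite = NULL,
                               low_specificity = character()) {
  stopifnot(is.data.frame(enzyme), all(c("ec", "status") %in% names(enzyme)))
  if (anyDuplicated(enzyme$ec))
    stop("duplicate E.C. number in enzyme table: ",
         enzyme$ec[duplicated(enzyme$ec)][1])
  check_ids <- function(ids, re, what) {
    bad <- ids[!grepl(re, ids)]
    if (length(bad)) stop("malformed ", what, " ID: ", sQuote(bad[1]))
  }
  ec_to_go <- list(); ec_to_prosite <- list()
  if (!is.null(ec2go) && nrow(ec2go)) {
    check_ids(ec2go$go, GO_ID_RE, "GO")
    ec_to_go <- lapply(split(ec2go$go, ec2go$ec), unique)
  }
  if (!is.null(ec2prosite) && nrow(ec2prosite)) {
    check_ids(ec2prosite$ps, PS_ID_RE, "PROSITE")
    ec_to_prosite <- lapply(split(ec2prosite$ps, ec2prosite$ec), unique)
  }
  st <- enzyme$status
  names(st) <- enzyme$ec
  structure(list(ec_status = st, ec_to_go = ec_to_go,
                 ec_to_prosite = ec_to_prosite,
                 low_specificity = low_specificity),
            class = "descriptor_mapping")
}

#' Flatten PROSITE-entry E.C. cross-references
#'
#' @param prosite Data frame from [read_prosite_dat()].
#' @return Data frame with columns `ec`, `ps`, one row per reference.
#' @export
prosite_ec_links <- function(prosite) {
  n <- vapply(prosite$ec, length, 1L)
  data.frame(ec = unlist(prosite$ec, use.names = FALSE),
             ps = rep(prosite$ac, n), stringsAsFactors = FALSE)
}

known_ecs <- function(mapping) {
  unique(c(names(mapping$ec_status), names(mapping$ec_to_go),
           names(mapping$ec_to_prosite)))
}

#' Expand wildcards and filter E.C. numbers by status
#'
#' Wildcard entries (`1.1.1.*`) expand to every concrete E.C. number in
#' the mapping sharing their first three fields (a warning is raised for
#' an empty expansion). Duplicates are removed preserving first
#' occurrence; numbers whose status is not *active* are moved to
#' `dropped_by_status`. Concrete numbers absent from the mapping are kept
#' and recorded as unmapped.
#'
#' @param ecs Data frame from [parse_ec_list()] (or a character vector of
#'   concrete/wildcard tokens).
#' @param mapping A [descriptor_mapping()].
#' @return Object of class `ec_translation` (partial): list with
#'   `input_count`, `entries` (per expanded E.C.: `ec`, `group`, `status`,
#'   `first`), `nonredundant_ecs`, `dropped_by_status`, `unmapped`.
#' @export
expand_and_filter <- function(ecs, mapping) {
  if (is.character(ecs))
    ecs <- data.frame(ec = ecs, group = rep(NA_character_, length(ecs)),
                      stringsAsFactors = FALSE)
  stopifnot(inherits(mapping, "descriptor_mapping"))
  pool <- known_ecs(mapping)
  out_ec <- character(); out_grp <- character()
  for (i in seq_len(nrow(ecs))) {
    tok <- ecs$ec[i]
    if (is_ec_wildcard(tok)) {
      hits <- pool[ec_prefix(pool) == ec_prefix(tok)]
      if (length(hits) == 0L) {
        warning("wildcard ", sQuote(tok), " matches no E.C. number in the mapping")
        next
      }
      out_ec <- c(out_ec, sort(hits))
      out_grp <- c(out_grp, rep(ecs$group[i], length(hits)))
    } else {
      out_ec <- c(out_ec, tok)
      out_grp <- c(out_grp, ecs$group[i])
    }
  }
  first <- !duplicated(out_ec)
  status <- mapping$ec_status[out_ec]
  status[is.na(status)] <- "active"  # unmapped default to active
  entries <- data.frame(ec = out_ec, group = out_grp,
                        status = unname(status), first = first,
                        stringsAsFactors = FALSE)
  nr <- out_ec[first]
  nr_status <- entries$status[first]
  structure(list(
    input_count = nrow(ecs),
    entries = entries,
    nonredundant_ecs = nr[nr_status == "active"],
    dropped_by_status = nr[nr_status != "active"],
    unmapped = setdiff(nr, names(mapping$ec_status))),
    class = "ec_translation")
}

#' Translate surviving E.C. numbers into descriptor filter lists
#'
#' Completes an [expand_and_filter()] result: the GO profile is the
#' deduplicated union of mapped GO terms over the active non-redundant
#' E.C. numbers (first-occurrence order); the PROSITE pattern list is the
#' analogous union minus the mapping's low-specificity IDs (logged in
#' `dropped_low_specificity`). Supplemental descriptors for non-enzyme
#' POIs (e.g. aquaporin) are appended from `supplemental`.
#'
#' @param tr An `ec_translation` from [expand_and_filter()].
#' @param mapping A [descriptor_mapping()].
#' @param supplemental Optional data frame with columns `group`, `kind`
#'   (`"go"` or `"prosite"`), `id`.
#' @return The completed `ec_translation`: adds `go_profile`,
#'   `prosite_pattern_list`, `dropped_low_specificity` and
#'   `per_group_counts` (per POI group: `ec_total`, `ec_nonredundant`,
#'   `ec_active`, `go_total`, `go_nonredundant`, `prosite_total`,
#'   `prosite_nonredundant`).
#' @export
translate_descriptors <- function(tr, mapping, supplemental = NULL) {
  stopifnot(inherits(tr, "ec_translation"), inherits(mapping, "descriptor_mapping"))
  active <- tr$nonredundant_ecs
  go_all <- unlist(lapply(active, function(e) mapping$ec_to_go[[e]]),
                   use.names = FALSE)
  ps_all <- unlist(lapply(active, function(e) mapping$ec_to_prosite[[e]]),
                   use.names = FALSE)
  sup_go <- character(); sup_ps <- character()
  if (!is.null(supplemental) && nrow(supplemental)) {
    stopifnot(all(c("group", "kind", "id") %in% names(supplemental)))
    sup_go <- supplemental$id[supplemental$kind == "go"]
    sup_ps <- supplemental$id[supplemental$kind == "prosite"]
  }
  go_profile <- unique(c(go_all, sup_go))
  ps_nr <- unique(c(ps_all, sup_ps))
  dropped <- intersect(ps_nr, mapping$low_specificity)
  tr$go_profile <- go_profile
  tr$prosite_pattern_list <- setdiff(ps_nr, mapping$low_specificity)
  tr$dropped_low_specificity <- dropped
  tr$per_group_counts <- per_group_counts(tr, mapping, supplemental)
  tr
}

per_group_counts <- function(tr, mapping, supplemental) {
  e <- tr$entries
  groups <- unique(c(e$group[!is.na(e$group)],
                     if (!is.null(supplemental)) supplemental$group))
  if (length(groups) == 0L) groups <- NA_character_
  rows <- lapply(groups, function(g) {
    in_g <- if (is.na(g)) is.na(e$group) else !is.na(e$group) & e$group == g
    sub <- e[in_g, , drop = FALSE]
    nr <- unique(sub$ec)
    act <- nr[mapping$ec_status[nr] %in% "active" | !(nr %in% names(mapping$ec_status))]
    act <- intersect(act, tr$nonredundant_ecs)
    gos <- unlist(lapply(act, function(x) mapping$ec_to_go[[x]]), use.names = FALSE)
    pss <- unlist(lapply(act, function(x) mapping$ec_to_prosite[[x]]), use.names = FALSE)
    if (!is.null(supplemental) && nrow(supplemental)) {
      sup <- supplemental[supplemental$group %in% g, , drop = FALSE]
      gos <- c(gos, sup$id[sup$kind == "go"])
      pss <- c(pss, sup$id[sup$kind == "prosite"])
    }
    data.frame(group = g, ec_total = nrow(sub), ec_nonredundant = length(nr),
               ec_active = length(act),
               go_total = length(gos), go_nonredundant = length(unique(gos)),
               prosite_total = length(pss),
               prosite_nonredundant =
                 length(setdiff(unique(pss), mapping$low_specificity)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ec_translation <- function(x, ...) {
  cat("E.C. translation:", x$input_count, "input entries ->",
      length(x$nonredundant_ecs), "non-redundant active E.C. numbers\n")
  cat("  dropped by status:", length(x$dropped_by_status),
      "; unmapped:", length(x$unmapped), "\n")
  if (!is.null(x$go_profile))
    cat("  profile:", length(x$go_profile), "GO terms; pattern:",
        length(x$prosite_pattern_list), "PROSITE IDs (",
        length(x$dropped_low_specificity), "low-specificity dropped )\n")
  invisible(x)
}

#' Write and read descriptor filter lists
#'
#' The filter-list document is a flat TSV: a header line naming the
#' descriptor kind (`go_term` or `prosite_id`) followed by one descriptor
#' ID per line. [emit_filter_lists()] writes the profile and pattern
#' documents of a completed translation; [read_filter_list()] loads one
#' back (round-trip safe, preserving order).
#'
#' @param tr A completed `ec_translation` ([translate_descriptors()]).
#' @param go_path,prosite_path Destination files.
#' @return `emit_filter_lists()` returns the two paths invisibly;
#'   `read_filter_list()` returns the character vector of IDs with an
#'   attribute `kind`.
#' @export
emit_filter_lists <- function(tr, go_path, prosite_path) {
  stopifnot(inherits(tr, "ec_translation"), !is.null(tr$go_profile))
  writeLines(c("go_term", tr$go_profile), go_path)
  writeLines(c("prosite_id", tr$prosite_pattern_list), prosite_path)
  invisible(c(go_path, prosite_path))
}

#' @rdname emit_filter_lists
#' @param path Filter-list file to read.
#' @export
read_filter_list <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !(lines[1] %in% c("go_term", "prosite_id")))
    stop("not a filter-list document (expected a 'go_term' or 'prosite_id' header): ",
         path)
  ids <- lines[-1][nzchar(lines[-1])]
  attr(ids, "kind") <- if (lines[1] == "go_term") "profile" else "pattern"
  ids
}
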