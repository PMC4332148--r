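# Subunit / complex catalog ----------------------------------------------

# Greek letters used in the canonical nomenclature; sources stay ASCII.
.alpha <- "α"
.beta <- "β"
.gamma <- "γ"

#' Canonical subunit names
#'
#' Convenience constructors for the canonical proteasome subunit labels used
#' throughout the package, so that callers do not need to type Greek letters.
#'
#' @param i integer index or index string such as `"2i"`.
#' @return A character scalar such as `"α6"` or `"β2i"`.
#' @examples
#' alpha_subunit(6)
#' beta_subunit("2i")
#' @export
alpha_subunit <- function(i) paste0(.alpha, i)

#' @rdname alpha_subunit
#' @export
beta_subunit <- function(i) paste0(.beta, i)

#' Read a subunit catalog from TSV
#'
#' The catalog is a plain-text TSV with columns `subunit_name`, `accession`
#' and `aliases` (semicolon-separated). Subunit names and accessions must be
#' unique and every alias must resolve to exactly one subunit.
#'
#' @param path path to the TSV file.
#' @return An object of class `subunit_catalog`: a list with `entries`
#'   (data.frame) and `alias_map` (named character, alias -> subunit_name).
#' @export
read_subunit_catalog <- function(path) {
  df <- read_tsv_utf8(path)
  stopifnot(all(c("subunit_name", "accession", "aliases") %in% names(df)))
  new_subunit_catalog(df$subunit_name, df$accession, df$aliases)
}

# TSV reader that keeps strings as declared UTF-8 regardless of locale
read_tsv_utf8 <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df[] <- lapply(df, function(col)
    if (is.character(col)) enc2utf8(col) else col)
  df
}

new_subunit_catalog <- function(subunit_name, accession, aliases) {
  if (anyDuplicated(subunit_name))
    stop("duplicate subunit names: ",
         paste(unique(subunit_name[duplicated(subunit_name)]), collapse = ", "))
  if (anyDuplicated(accession))
    stop("duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  entries <- data.frame(subunit_name = subunit_name, accession = accession,
                        aliases = aliases, stringsAsFactors = FALSE)
  alias_list <- strsplit(ifelse(is.na(aliases), "", aliases), ";", fixed = TRUE)
  alias_map <- stats::setNames(
    rep(subunit_name, lengths(alias_list)), unlist(alias_list))
  # names themselves resolve, too
  alias_map <- c(stats::setNames(subunit_name, subunit_name), alias_map)
  dup <- names(alias_map)[duplicated(names(alias_map)) &
                            !duplicated(paste(names(alias_map), alias_map))]
  if (length(dup))
    stop("alias resolves to more than one subunit: ",
         paste(unique(dup), collapse = ", "))
  structure(list(entries = entries, alias_map = alias_map),
            class = "subunit_catalog")
}

#' @export
print.subunit_catalog <- function(x, ...) {
  cat("subunit_catalog with", nrow(x$entries), "subunits\n")
  invisible(x)
}

#' Resolve names or aliases to canonical subunit names
#'
#' @param names character vector of subunit names, aliases or accessions.
#' @param catalog a `subunit_catalog`.
#' @return Character vector of canonical subunit names, same length as
#'   `names`. Unresolvable names raise an error listing all offenders rather
#'   than being silently dropped.
#' @export
resolve_subunits <- function(names, catalog) {
  stopifnot(inherits(catalog, "subunit_catalog"))
  if (length(names) == 0L) return(character(0))
  acc_map <- stats::setNames(catalog$entries$subunit_name,
                             catalog$entries$accession)
  out <- unname(catalog$alias_map[names])
  miss <- is.na(out)
  out[miss] <- unname(acc_map[names[miss]])
  if (anyNA(out))
    stop("unresolvable subunit name(s): ",
         paste(unique(names[is.na(out)]), collapse = ", "))
  out
}

#' Map canonical subunit names to accessions
#'
#' @inheritParams resolve_subunits
#' @return Character vector of accessions.
#' @export
subunit_accessions <- function(names, catalog) {
  canon <- resolve_subunits(names, catalog)
  map <- stats::setNames(catalog$entries$accession, catalog$entries$subunit_name)
  unname(map[canon])
}

#' Define a reference complex
#'
#' A reference complex is a named set of subunits plus the rule used to
#' aggregate the members' abundances into a single reference abundance.
#'
#' @param name complex name, e.g. `"ncP20S"`.
#' @param members character vector of subunit names (non-empty).
#' @param aggregation one of `"median"`, `"mean"`, `"single"`. `"single"`
#'   requires exactly one member.
#' @return Object of class `complex_definition`.
#' @export
complex_definition <- function(name, members,
                               aggregation = c("median", "mean", "single")) {
  aggregation <- match.arg(aggregation)
  if (length(members) < 1L) stop("complex '", name, "' has no members")
  if (aggregation == "single" && length(members) != 1L)
    stop("complex '", name, "': aggregation 'single' requires exactly one member")
  structure(list(name = name, members = members, aggregation = aggregation),
            class = "complex_definition")
}

#' @export
print.complex_definition <- function(x, ...) {
  cat(sprintf("complex '%s' (%s of %d member%s)\n", x$name, x$aggregation,
              length(x$members), if (length(x$members) == 1) "" else "s"))
  invisible(x)
}

#' Read complex definitions from TSV
#'
#' TSV columns: `complex_name`, `aggregation`, `members`
#' (semicolon-separated subunit names). All members must resolve in the
#' catalog.
#'
#' @param path path to the TSV file.
#' @param catalog a `subunit_catalog` used to validate members.
#' @return Named list of `complex_definition` objects.
#' @export
read_complex_definitions <- function(path, catalog) {
  df <- read_tsv_utf8(path)
  stopifnot(all(c("complex_name", "aggregation", "members") %in% names(df)))
  defs <- lapply(seq_len(nrow(df)), function(i) {
    members <- resolve_subunits(
      strsplit(df$members[i], ";", fixed = TRUE)[[1]], catalog)
    complex_definition(df$complex_name[i], members, df$aggregation[i])
  })
  stats::setNames(defs, df$complex_name)
}

#' Write a catalog / complex definitions back to TSV
#'
#' Round-trips losslessly with [read_subunit_catalog()] and
#' [read_complex_definitions()].
#'
#' @param catalog a `subunit_catalog`.
#' @param defs named list of `complex_definition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subunit_catalog <- function(catalog, path) {
  utils::write.table(catalog$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_subunit_catalog
#' @export
write_complex_definitions <- function(defs, path) {
  df <- data.frame(
    complex_name = vapply(defs, `[[`, "", "name"),
    aggregation = vapply(defs, `[[`, "", "aggregation"),
    members = vapply(defs, function(d) paste(d$members, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The default proteasome catalog and reference complexes
#'
#' Loads the catalog shipped with the package: the 20S core particle
#' subunits (alpha1-7, beta1-7 plus the three immunosubunits beta1i, beta2i,
#' beta5i), the 19S regulatory particle (Rpt1-6, Rpn1-3, Rpn5-14) and the
#' PA28alpha/beta, PA28gamma, PA200 and PI31 regulators, together with the
#' eight reference complex definitions used in the analysis:
#' \describe{
#'   \item{ncP20S}{median of the 11 non-catalytic 20S subunits (a proxy for
#'     total 20S core particle).}
#'   \item{19S}{median of the 19 regulatory-particle subunits.}
#'   \item{PA28αβ}{median of PA28α and PA28β.}
#'   \item{sP20S}{the β5 catalytic subunit (standard-proteasome proxy).}
#'   \item{iP20S}{the β2i catalytic subunit (immunoproteasome proxy).}
#'   \item{PA28γ, PA200, PI31}{single-chain regulators, used directly.}
#' }
#'
#' @return A list with elements `catalog` (`subunit_catalog`) and `complexes`
#'   (named list of `complex_definition`).
#' @examples
#' cat6 <- default_catalog()
#' length(cat6$complexes$ncP20S$members)  # 11
#' @export
default_catalog <- function() {
  sub_path <- system.file("extdata", "proteasome_subunits.tsv",
                          package = "proteoPCP", mustWork = TRUE)
  cx_path <- system.file("extdata", "proteasome_complexes.tsv",
                         package = "proteoPCP", mustWork = TRUE)
  catalog <- read_subunit_catalog(sub_path)
  complexes <- read_complex_definitions(cx_path, catalog)
  list(catalog = catalog, complexes = complexes)
}

# subtype -> catalytic subunit composition of the 20S core particle;
# the 11 non-catalytic subunits are shared by all subtypes.
subtype_catalytic <- function() {
  list(
    sP20S = paste0(.beta, c("1", "2", "5")),
    iP20S = paste0(.beta, c("1i", "2i", "5i")),
    b5i_P20S = paste0(.beta, c("1", "2", "5i")),
    b1ib5i_P20S = paste0(.beta, c("1i", "2", "5i")))
}

noncatalytic_subunits <- function() {
  c(paste0(.alpha, 1:7), paste0(.beta, c(3, 4, 6, 7)))
}
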