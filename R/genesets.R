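#' Construct a gene set
#'
#' A gene set (term) is a named collection of gene symbols curated to
#' represent a function, pathway, module, or disease association. Gene
#' identifiers are opaque, case-sensitive strings; duplicate symbols are
#' collapsed (set semantics).
#'
#' @param name Term identifier, a non-empty string.
#' @param genes Character vector of member gene symbols; duplicates are
#'   collapsed, empty strings dropped. Must be non-empty after cleaning.
#' @param description Free-text description (may be empty).
#' @param resource Name of the source resource (may be empty).
#' @return An object of class `gene_set` with fields `name`, `description`,
#'   `genes` (unique character vector) and `resource`.
#' @examples
#' gene_set("TermA", c("G1", "G2", "G2"))
#' @export
gene_set <- function(name, genes, description = "", resource = "") {
  if (!is_string(name) || !nzchar(name)) stop_tn("gene set 'name' must be a non-empty string")
  if (!is.character(genes)) stop_tn("'genes' must be a character vector")
  genes <- unique(genes[!is.na(genes) & nzchar(genes)])
  if (length(genes) == 0L) {
    stop_tn("gene set '", name, "' has no member genes")
  }
  if (!is_string(description)) description <- ""
  structure(
    list(name = name, description = description, genes = genes, resource = resource),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set> %s [%s]: %d genes\n", x$name,
    if (nzchar(x$resource)) x$resource else "?", length(x$genes)
  ))
  invisible(x)
}

#' Construct a gene set resource
#'
#' A resource is an ordered, named collection of gene sets (typically one GMT
#' file). Term names must be unique within a resource. The resource universe
#' is the union of all member genes.
#'
#' @param sets List of [gene_set()] objects.
#' @param name Resource name, a non-empty string.
#' @return An object of class `geneset_resource` with fields `name`, `sets`
#'   (named list, in input order) and `universe` (character vector, union of
#'   all member genes).
#' @export
geneset_resource <- function(sets, name) {
  if (!is_string(name) || !nzchar(name)) stop_tn("resource 'name' must be a non-empty string")
  if (!is.list(sets) || length(sets) == 0L) stop_tn("resource '", name, "' has no genesets")
  ok <- vapply(sets, inherits, logical(1L), "gene_set")
  if (!all(ok)) stop_tn("'sets' must be a list of gene_set objects")
  nms <- vapply(sets, `[[`, character(1L), "name")
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop_tn("duplicate term name(s) in resource '", name, "': ", paste(unique(dup), collapse = ", "))
  }
  sets <- lapply(sets, function(s) { s$resource <- name; s })
  names(sets) <- nms
  structure(
    list(name = name, sets = sets, universe = unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))),
    class = "geneset_resource"
  )
}

#' @export
print.geneset_resource <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1L))
  cat(sprintf(
    "<geneset_resource> %s: %d terms (sizes %d-%d), universe %d genes\n",
    x$name, length(x$sets), min(sizes), max(sizes), length(x$universe)
  ))
  invisible(x)
}

#' @export
length.geneset_resource <- function(x) length(x$sets)

#' Universe of one or more gene set resources
#'
#' @param resources A `geneset_resource` or list of them.
#' @return Character vector: union of member genes across all terms.
#' @export
resource_universe <- function(resources) {
  resources <- as_resource_list(resources)
  unique(unlist(lapply(resources, `[[`, "universe"), use.names = FALSE))
}

# accept a single resource or a list of resources
as_resource_list <- function(resources) {
  if (inherits(resources, "geneset_resource")) resources <- list(resources)
  if (!is.list(resources) || length(resources) == 0L ||
      !all(vapply(resources, inherits, logical(1L), "geneset_resource"))) {
    stop_tn("expected a geneset_resource or a non-empty list of them")
  }
  resources
}

# flatten resources into one data.frame of term descriptors + list of gene vectors
flatten_terms <- function(resources) {
  resources <- as_resource_list(resources)
  rows <- do.call(rbind, lapply(seq_along(resources), function(i) {
    r <- resources[[i]]
    data.frame(
      resource = r$name, term = names(r$sets),
      size = vapply(r$sets, function(s) length(s$genes), integer(1L)),
      resource_idx = i, stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  rows$genes <- unlist(lapply(resources, function(r) lapply(r$sets, `[[`, "genes")),
                       recursive = FALSE, use.names = FALSE)
  rows
}
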