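# Gene-set (GMT) handling and per-person QV burden profiles.

#' Construct a gene-set collection
#'
#' A collection is a named list of unique gene-symbol vectors with an
#' optional description per set (Broad GMT semantics). Duplicate genes
#' within a set are removed with a warning; empty sets are rejected.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return named list of class `gene_set_collection` with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  for (i in seq_along(sets)) {
    genes <- trimws(as.character(sets[[i]]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("gene set '", names(sets)[i], "' is empty", call. = FALSE)
    }
    if (anyDuplicated(genes)) {
      warning("duplicate genes removed from set '", names(sets)[i], "'")
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Read a GMT file
#'
#' Broad dialect: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected name, description and ",
           "at least one gene", call. = FALSE)
    }
    sets[[fields[1]]] <- fields[-(1:2)]
    descs <- c(descs, fields[2])
  }
  gene_set_collection(sets, descs)
}

#' Write a gene-set collection to GMT
#' @param collection [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descs[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Exclusive-region counts for a group of gene sets
#'
#' Venn-style decomposition: for every non-empty combination of the chosen
#' sets, the number of genes belonging to exactly that combination. Region
#' counts sum to the union size.
#'
#' @param collection [gene_set_collection()].
#' @param set_names sets to intersect (default: all).
#' @return named integer vector; names are `&`-joined set-name combinations.
#' @export
collection_overlap <- function(collection, set_names = names(collection)) {
  unknown <- setdiff(set_names, names(collection))
  if (length(unknown) > 0L) {
    stop("unknown set name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  universe <- unique(unlist(collection[set_names]))
  membership <- vapply(set_names, function(nm) universe %in% collection[[nm]],
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, set_names))
  region <- apply(membership, 1L, function(row) {
    paste(set_names[row], collapse = "&")
  })
  counts <- table(region)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Restrict gene sets to genes harbouring qualifying variants
#'
#' Each set is reduced to its genes with at least one QV in the cohort.
#' Sets left empty are dropped and reported in `attr(, "empty_sets")`.
#' The operation is idempotent.
#'
#' @param collection [gene_set_collection()].
#' @param qvset result of [qualify_variants()].
#' @return restricted `gene_set_collection` (possibly with fewer sets).
#' @export
restrict_to_qv_genes <- function(collection, qvset) {
  genes <- qv_genes(qvset)
  restricted <- lapply(collection, function(s) intersect(s, genes))
  empty <- names(restricted)[vapply(restricted, length, integer(1)) == 0L]
  restricted <- restricted[setdiff(names(restricted), empty)]
  if (length(restricted) == 0L) {
    out <- structure(list(), descriptions = character(0),
                     class = "gene_set_collection")
  } else {
    out <- gene_set_collection(
      restricted, attr(collection, "descriptions")[names(restricted)])
  }
  attr(out, "empty_sets") <- empty
  out
}

#' Per-person QV burden per gene set
#'
#' Under the dominant inheritance model a person's burden in a gene set is
#' the number of distinct qualifying sites in the set's genes at which they
#' carry at least one alternate allele (a homozygous site counts once);
#' `carrier` is burden >= 1. A `dosage_sum` mode (summing allele dosages)
#' is provided for sensitivity analysis. Samples whose genotypes are missing
#' at every qualifying site of a set get `NA` burden and carrier status.
#'
#' @param qvset result of [qualify_variants()].
#' @param genotypes dosage matrix (samples x variants).
#' @param catalog variant catalog.
#' @param collection [gene_set_collection()].
#' @param mode `"carrier_sites"` (default, dominant-model site count) or
#'   `"dosage_sum"`.
#' @return data.frame of class `burden_profile`: `sample_id`, `set_name`,
#'   `qv_count`, `carrier`.
#' @export
burden_profile <- function(qvset, genotypes, catalog, collection,
                           mode = c("carrier_sites", "dosage_sum")) {
  mode <- match.arg(mode)
  stopifnot(ncol(genotypes) == nrow(catalog))
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  qv <- catalog$variant_id %in% qv_ids(qvset)
  rows <- list()
  for (set_name in names(collection)) {
    idx <- which(qv & catalog$gene %in% collection[[set_name]])
    if (length(idx) == 0L) {
      qv_count <- rep(0L, nrow(genotypes))
      all_missing <- rep(FALSE, nrow(genotypes))
    } else {
      sub <- genotypes[, idx, drop = FALSE]
      contrib <- if (mode == "carrier_sites") (sub >= 1L) * 1L else sub
      qv_count <- as.integer(rowSums(contrib, na.rm = TRUE))
      all_missing <- rowSums(!is.na(sub)) == 0L
    }
    qv_count[all_missing] <- NA_integer_
    rows[[set_name]] <- data.frame(
      sample_id = samples, set_name = set_name, qv_count = qv_count,
      carrier = qv_count >= 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("burden_profile", "data.frame")
  out
}

#' Per-gene carrier status at qualifying sites
#'
#' For each listed gene, flags each sample carrying >= 1 alternate allele at
#' any qualifying site of that gene. `NA` when all the gene's qualifying
#' genotypes are missing for the sample.
#'
#' @param qvset result of [qualify_variants()].
#' @param genotypes dosage matrix (samples x variants).
#' @param catalog variant catalog.
#' @param genes gene symbols (default: all QV genes).
#' @return logical matrix, samples x genes.
#' @export
carrier_by_gene <- function(qvset, genotypes, catalog, genes = qv_genes(qvset)) {
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  qv <- catalog$variant_id %in% qv_ids(qvset)
  out <- matrix(NA, nrow = nrow(genotypes), ncol = length(genes),
                dimnames = list(samples, genes))
  for (j in seq_along(genes)) {
    idx <- which(qv & catalog$gene == genes[j])
    if (length(idx) == 0L) { out[, j] <- FALSE; next }
    sub <- genotypes[, idx, drop = FALSE]
    carrier <- rowSums(sub >= 1L, na.rm = TRUE) > 0L
    carrier[rowSums(!is.na(sub)) == 0L] <- NA
    out[, j] <- carrier
  }
  out
}
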