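#' Read a pedigree file
#'
#' Reads a delimiter-separated pedigree with header.  Required columns:
#' `animal`, `sire`, `dam`; any further columns (birth_year, farm,
#' season, sex, mgmt_group, composition_code, ...) are carried through.
#' Missing parents are encoded by a sentinel token (`"0"` by livestock
#' convention) or by empty/NA fields.  Parents that are referenced but
#' never listed are appended as founder rows.
#'
#' @param path Path to the file.
#' @param sep Field separator (`"\t"` default; `""` splits on any
#'   whitespace).
#' @param missing_parent Sentinel token for unknown parents.
#' @return A `data.frame` with character `animal`, `sire`, `dam` (`NA`
#'   for unknown) plus any extra columns; appended founders carry `NA`
#'   in the extra columns.
#' @export
read_pedigree <- function(path, sep = "\t", missing_parent = "0") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  ped <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  for (cl in c("sire", "dam")) {
    x <- ped[[cl]]
    x[x == missing_parent | x == "" | is.na(x)] <- NA_character_
    ped[[cl]] <- x
  }
  ped$animal <- as.character(ped$animal)
  if (anyDuplicated(ped$animal)) {
    stop("duplicate animal id(s) in pedigree file: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  ## append referenced-but-unlisted parents as founders
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  extra <- setdiff(parents, ped$animal)
  if (length(extra)) {
    add <- ped[rep(NA_integer_, length(extra)), , drop = FALSE]
    add$animal <- extra
    add$sire <- NA_character_
    add$dam <- NA_character_
    rownames(add) <- NULL
    ped <- rbind(ped, add)
  }
  rownames(ped) <- NULL
  ## fail fast on cycles (order_pedigree errors with the cycle member)
  invisible(order_pedigree(ped))
  ped
}

#' Write a pedigree file
#'
#' @param ped Pedigree `data.frame` as returned by [read_pedigree()].
#' @param path Output path.
#' @param missing_parent Sentinel written for unknown parents.
#' @export
write_pedigree <- function(ped, path, missing_parent = "0") {
  out <- ped
  for (cl in c("sire", "dam")) out[[cl]][is.na(out[[cl]])] <- missing_parent
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genotype matrix container
#'
#' Bundles an animals-by-SNPs allele-count matrix (values 0/1/2, `NA`
#' missing) with its SNP map.
#'
#' @param geno Integer/numeric matrix, rows = animals (rownames = ids),
#'   columns = SNPs.
#' @param map `data.frame` with columns `snp_id`, `chrom` (integer),
#'   `pos` (bp).
#' @return Object of class `genomat`.
#' @export
genotype_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  stopifnot(!is.null(rownames(geno)))
  if (ncol(geno) != nrow(map)) {
    stop("genotype width (", ncol(geno), ") does not match map length (",
         nrow(map), ")")
  }
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("genotype codes outside {0,1,2,NA}: e.g. ",
                     geno[which(bad)[1]])
  storage.mode(geno) <- "integer"
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.integer(map$pos)
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map), class = "genomat")
}

#' @export
print.genomat <- function(x, ...) {
  cat(sprintf("<genomat: %d animals x %d SNPs on %d chromosome(s)>\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Read genotypes from a matrix + map TSV pair or PLINK .raw
#'
#' With a path prefix `p`, reads `p.geno.tsv` (first column `animal_id`,
#' one column per SNP, allele counts with `NA` or `5` as missing) and
#' `p.map.tsv` (columns `snp_id`, `chrom`, `pos`).  If `p.raw` exists
#' instead, the PLINK `--recode A` layout is parsed (FID IID PAT MAT SEX
#' PHENOTYPE then one allele-count column per SNP) and the map is read
#' from `p.map.tsv`.
#'
#' @param path_prefix Path prefix without extension.
#' @return A [genotype_matrix()] with animal ids in input order.
#' @export
read_genotypes <- function(path_prefix) {
  map_path <- paste0(path_prefix, ".map.tsv")
  if (!file.exists(map_path)) stop("SNP map not found: ", map_path)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  raw_path <- paste0(path_prefix, ".raw")
  if (file.exists(raw_path)) {
    tab <- utils::read.table(raw_path, header = TRUE, sep = "",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab$IID)
    geno <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    gpath <- paste0(path_prefix, ".geno.tsv")
    if (!file.exists(gpath)) stop("genotype file not found: ", gpath)
    tab <- utils::read.table(gpath, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    geno <- as.matrix(tab[, -1, drop = FALSE])
  }
  if (!is.numeric(geno)) stop("non-numeric genotype code in ", path_prefix)
  geno[geno == 5] <- NA  # alternative missing code
  if (any(geno != round(geno), na.rm = TRUE)) {
    stop("non-integer genotype code in ", path_prefix)
  }
  if (ncol(geno) != nrow(map)) {
    stop("genotype width (", ncol(geno), ") does not match map length (",
         nrow(map), ") for ", path_prefix)
  }
  rownames(geno) <- ids
  genotype_matrix(geno, map)
}

#' Write genotypes as a matrix + map TSV pair
#'
#' @param g A `genomat`.
#' @param path_prefix Output path prefix (writes `.geno.tsv` and
#'   `.map.tsv`).
#' @export
write_genotypes <- function(g, path_prefix) {
  stopifnot(inherits(g, "genomat"))
  utils::write.table(g$map, paste0(path_prefix, ".map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tab <- data.frame(animal_id = rownames(g$geno), g$geno,
                    check.names = FALSE)
  utils::write.table(tab, paste0(path_prefix, ".geno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path_prefix)
}

#' Read a gene annotation file (BED or GFF3)
#'
#' Intervals are normalized to 1-based closed coordinates (BED input is
#' 0-based half-open and is shifted by the importer) so they are directly
#' comparable with SNP map positions.
#'
#' @param path Path to a `.bed`, `.gff3` or `.gff` file.
#' @param feature For GFF input, keep only rows of this `type` (default
#'   `"gene"`; `NULL` keeps everything).
#' @return `data.frame` with columns `chrom` (character), `start`, `end`
#'   (1-based closed), `gene_id`, `strand`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(feature) && "type" %in% names(df)) {
    keep <- df$type == feature
    if (any(keep)) df <- df[keep, , drop = FALSE]
  }
  id <- if ("gene_id" %in% names(df)) df$gene_id
        else if ("Name" %in% names(df)) df$Name
        else if ("ID" %in% names(df)) df$ID
        else if ("name" %in% names(df)) df$name
        else paste0("gene", seq_len(nrow(df)))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    gene_id = as.character(id),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed interval (start > end) in ", path)
  rownames(out) <- NULL
  out
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated with header, floats at fixed precision, rows in the
#' order given; re-running on the same input yields a byte-identical
#' file.
#'
#' @param results A `data.frame`.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @export
write_report <- function(results, path, digits = 6) {
  stopifnot(is.data.frame(results))
  out <- results
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- formatC(out[[cl]], format = "f", digits = digits)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
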