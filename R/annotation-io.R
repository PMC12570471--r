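# Readers and writers for the two standard annotation carriers: the NCBI
# assembly *_feature_table.txt dialect and GFF3. Both store 1-based
# inclusive coordinates, which is also the internal convention, so values
# are copied verbatim.

RNA_CLASSES <- c("tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA", "SRP_RNA",
                 "RNase_P_RNA", "antisense_RNA", "RNA")

#' Parse an NCBI assembly feature table
#'
#' Reads the tab-separated `*_feature_table.txt[.gz]` file that NCBI ships
#' with every assembly. Rows are grouped by `locus_tag`; a protein-coding
#' gene typically appears as a gene/CDS row pair and the CDS row's
#' coordinates are taken as authoritative (the diff downstream compares
#' predicted transcript extents). `old_locus_tag` entries in the attributes
#' column are split on commas and preserved as a list.
#'
#' @param path Path to the feature table (may be gzip-compressed).
#' @param source_label Label for the release (e.g. `"GenBank"`).
#' @param accession,retrieval_date Optional provenance metadata.
#' @return A [genome_annotation()].
#' @export
parse_feature_table <- function(path, source_label,
                                accession = NA_character_,
                                retrieval_date = NA_character_) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"))
  names(raw)[1L] <- sub("^#\\s*", "", names(raw)[1L])
  required <- c("feature", "class", "start", "end", "strand", "locus_tag")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop_annodiff("feature table %s is missing mandatory column(s): %s",
                  path, paste(missing, collapse = ", "))
  }
  for (col in c("attributes", "name", "symbol", "genomic_accession",
                "chromosome")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }

  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  tagged <- raw[!is.na(raw$locus_tag), ]

  gene_rows <- tagged[tagged$feature == "gene", ]
  dup <- unique(gene_rows$locus_tag[duplicated(gene_rows$locus_tag)])
  if (length(dup) > 0L) {
    stop_annodiff("duplicate locus_tag(s) in %s: %s", path,
                  paste(head(dup, 20L), collapse = ", "))
  }

  feats <- tagged |>
    dplyr::group_by(.data$locus_tag) |>
    dplyr::summarise(
      feature_class = classify_ft_rows(.data$feature, .data$class),
      start = ft_coord(.data$feature, .data$class, .data$start, min),
      end = ft_coord(.data$feature, .data$class, .data$end, max),
      strand = .data$strand[1L],
      product_name = first_nonempty(
        c(.data$name[.data$feature == "CDS"], .data$name)),
      gene_symbol = first_nonempty(.data$symbol),
      sequence_id = first_nonempty(
        c(.data$genomic_accession, .data$chromosome, "seq1")),
      old_locus_tags = list(extract_old_tags(.data$attributes)),
      .groups = "drop"
    )
  # preserve file order of first appearance
  feats <- feats[order(match(feats$locus_tag, tagged$locus_tag)), ]

  genome_annotation(feats, source_label = source_label,
                    accession = accession, retrieval_date = retrieval_date)
}

# class for a locus_tag group of feature-table rows
classify_ft_rows <- function(feature, class) {
  class <- class[!is.na(class)]
  if (any(class %in% c("protein_coding", "with_protein"))) return("protein_coding")
  if (any(class == "pseudogene" | class == "without_protein")) return("pseudo")
  if (any(class %in% RNA_CLASSES) || any(feature %in% RNA_CLASSES)) return("rna")
  "other"
}

# CDS coordinates when present, else the widest span of the group
ft_coord <- function(feature, class, coord, fn) {
  is_cds <- feature == "CDS" & !is.na(coord)
  if (any(is_cds)) fn(coord[is_cds]) else fn(coord, na.rm = TRUE)
}

first_nonempty <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0L) NA_character_ else x[1L]
}

extract_old_tags <- function(attributes) {
  hits <- regmatches(attributes,
                     regexpr("old_locus_tag=[^;]+", attributes))
  if (length(hits) == 0L) return(character(0))
  unique(unlist(strsplit(sub("^old_locus_tag=", "", hits), ",", fixed = TRUE)))
}

#' Parse a GFF3 annotation
#'
#' Imports a GFF3 file through [rtracklayer::import()] and retains gene-level
#' records carrying a `locus_tag` attribute. Feature classes are taken from
#' the `gene_biotype` attribute when present (NCBI convention), otherwise
#' from the record type. GFF3 coordinates are 1-based inclusive and copied
#' verbatim.
#'
#' @inheritParams parse_feature_table
#' @return A [genome_annotation()].
#' @export
parse_gff3 <- function(path, source_label,
                       accession = NA_character_,
                       retrieval_date = NA_character_) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      stop_annodiff("failed to parse GFF3 %s: %s", path, conditionMessage(e))
    }
  )
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(genome_annotation(empty_features(), source_label = source_label,
                             accession = accession,
                             retrieval_date = retrieval_date))
  }
  if (!"locus_tag" %in% names(mc)) {
    stop_annodiff("GFF3 %s carries no locus_tag attributes", path)
  }
  # prefer gene records; fall back to whatever rows carry a locus_tag
  keep <- as.character(mc$type) == "gene"
  if (!any(keep)) keep <- !is.na(attr_first(mc$locus_tag))
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)

  tags <- attr_first(mc$locus_tag)
  if (all(is.na(tags))) {
    stop_annodiff("GFF3 %s carries no locus_tag attributes on gene records",
                  path)
  }
  biotype <- if ("gene_biotype" %in% names(mc)) {
    attr_first(mc$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  pseudo_attr <- if ("pseudo" %in% names(mc)) {
    tolower(attr_first(mc$pseudo)) %in% c("true", "1")
  } else {
    rep(FALSE, length(gr))
  }

  feats <- tibble::tibble(
    locus_tag = tags,
    old_locus_tags = attr_list(mc[["old_locus_tag"]], length(gr)),
    feature_class = classify_gff(biotype, as.character(mc$type), pseudo_attr),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    product_name = if ("product" %in% names(mc))
      attr_first(mc$product) else NA_character_,
    gene_symbol = if ("gene" %in% names(mc))
      attr_first(mc$gene) else NA_character_,
    sequence_id = as.character(GenomicRanges::seqnames(gr))
  )
  feats <- feats[!is.na(feats$locus_tag), ]
  genome_annotation(feats, source_label = source_label,
                    accession = accession, retrieval_date = retrieval_date)
}

classify_gff <- function(biotype, type, pseudo_attr) {
  out <- rep("other", length(type))
  src <- ifelse(is.na(biotype), type, biotype)
  out[src %in% c("protein_coding", "CDS", "gene")] <- "protein_coding"
  out[src %in% RNA_CLASSES] <- "rna"
  out[src == "pseudogene" | pseudo_attr] <- "pseudo"
  out
}

# rtracklayer returns plain character or CharacterList depending on
# multiplicity; normalize either to one string per record
attr_first <- function(x) {
  if (is.null(x)) return(NA_character_)
  if (methods::is(x, "CharacterList") || is.list(x)) {
    vapply(as.list(x), function(v) {
      if (length(v) == 0L) NA_character_ else as.character(v[[1L]])
    }, character(1))
  } else {
    as.character(x)
  }
}

attr_list <- function(x, n) {
  if (is.null(x)) return(rep(list(character(0)), n))
  if (methods::is(x, "CharacterList") || is.list(x)) {
    purrr::map(as.list(x), as.character)
  } else {
    purrr::map(as.character(x), function(v) {
      if (is.na(v)) character(0) else strsplit(v, ",", fixed = TRUE)[[1L]]
    })
  }
}

empty_features <- function() {
  tibble::tibble(
    locus_tag = character(0), old_locus_tags = list(),
    feature_class = character(0), start = integer(0), end = integer(0),
    strand = character(0), product_name = character(0),
    gene_symbol = character(0), sequence_id = character(0)
  )
}

#' Parse an annotation, sniffing the format
#'
#' Dispatches to [parse_feature_table()] or [parse_gff3()] based on the
#' file's first line (`# feature` header vs `##gff-version` pragma).
#'
#' @inheritParams parse_feature_table
#' @return A [genome_annotation()].
#' @export
parse_annotation <- function(path, source_label,
                             accession = NA_character_,
                             retrieval_date = NA_character_) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) == 0L) stop_annodiff("%s is empty", path)
  if (grepl("^##gff-version", first)) {
    parse_gff3(path, source_label, accession, retrieval_date)
  } else if (grepl("^#\\s*feature\t", first)) {
    parse_feature_table(path, source_label, accession, retrieval_date)
  } else {
    stop_annodiff(
      "cannot identify %s as a feature table or GFF3 from its first line",
      path)
  }
}

#' Write an annotation to GFF3 or plain TSV
#'
#' The GFF3 form round-trips through [parse_gff3()] field-by-field; the TSV
#' form is a flat per-feature export (one row per feature, `old_locus_tags`
#' comma-joined) for spreadsheet use.
#'
#' @param ann A [genome_annotation()].
#' @param path Output file path.
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("gff3", "tsv")) {
  stopifnot(inherits(ann, "genome_annotation"))
  format <- match.arg(format)
  f <- ann$features
  if (format == "tsv") {
    flat <- dplyr::mutate(
      f, old_locus_tags = vapply(.data$old_locus_tags, paste,
                                 character(1), collapse = ","))
    readr::write_tsv(flat, path, progress = FALSE)
    return(invisible(path))
  }
  biotype <- c(protein_coding = "protein_coding", pseudo = "pseudogene",
               rna = "ncRNA", other = "other")[f$feature_class]
  attrs <- paste0(
    "ID=", gff3_encode(f$locus_tag),
    ";locus_tag=", gff3_encode(f$locus_tag),
    ifelse(lengths(f$old_locus_tags) > 0L,
           paste0(";old_locus_tag=",
                  vapply(f$old_locus_tags,
                         function(x) paste(gff3_encode(x), collapse = ","),
                         character(1))),
           ""),
    ";gene_biotype=", biotype,
    ifelse(is.na(f$product_name), "",
           paste0(";product=", gff3_encode(f$product_name))),
    ifelse(is.na(f$gene_symbol), "",
           paste0(";gene=", gff3_encode(f$gene_symbol)))
  )
  lines <- c(
    "##gff-version 3",
    if (nrow(f) > 0L) {
      paste(f$sequence_id, ann$source_label, "gene", f$start, f$end,
            ".", f$strand, ".", attrs, sep = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

# percent-encode the characters GFF3 reserves inside attribute values
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

#' Write an annotation in the NCBI assembly feature-table dialect
#'
#' Emits the tab-separated `*_feature_table.txt` layout: one `gene` row per
#' feature plus a `CDS` row for protein-coding genes, with `old_locus_tag`
#' recorded in the attributes column. Output re-parses with
#' [parse_feature_table()] to an equal feature set.
#'
#' @inheritParams write_annotation
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  f <- ann$features
  gene_class <- c(protein_coding = "protein_coding", pseudo = "pseudogene",
                  rna = "ncRNA", other = "other")[f$feature_class]
  attrs <- ifelse(lengths(f$old_locus_tags) > 0L,
                  paste0("old_locus_tag=",
                         vapply(f$old_locus_tags, paste, character(1),
                                collapse = ",")),
                  "")
  row_tbl <- function(feature, class, name) {
    tibble::tibble(
      feature = feature, class = class,
      assembly = ann$accession %||% NA_character_,
      assembly_unit = "Primary Assembly", seq_type = "chromosome",
      chromosome = f$sequence_id, genomic_accession = f$sequence_id,
      start = f$start, end = f$end, strand = f$strand,
      product_accession = NA_character_,
      `non-redundant_refseq` = NA_character_,
      related_accession = NA_character_,
      name = name, symbol = f$gene_symbol, GeneID = NA_character_,
      locus_tag = f$locus_tag,
      feature_interval_length = f$end - f$start + 1L,
      product_length = NA_integer_, attributes = attrs
    )
  }
  genes <- row_tbl("gene", unname(gene_class), NA_character_)
  cds <- row_tbl("CDS", "with_protein", f$product_name)
  cds <- cds[f$feature_class == "protein_coding", ]
  out <- dplyr::bind_rows(genes, cds)
  out <- out[order(match(out$locus_tag, f$locus_tag),
                   match(out$feature, c("gene", "CDS"))), ]
  names(out)[1L] <- "# feature"
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
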