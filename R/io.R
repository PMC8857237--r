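# Readers and writers for every format the pipeline consumes, plus the
# end-to-end driver. Formats: Roary-style presence/absence CSV, expression
# TSV, GFF3 gene models (rtracklayer), genome FASTA (Biostrings), per-strain
# VCF (vcfR for reading), assay CSV, phenotype TSV, JSON reports.

ROARY_META_COLS <- c(
  "Non-unique Gene name", "No. isolates", "No. sequences",
  "Avg sequences per isolate", "Genome Fragment", "Order within Fragment",
  "Accessory Fragment", "Accessory Order with Fragment", "QC",
  "Min group size nuc", "Max group size nuc", "Avg group size nuc")

#' Read a Roary-style gene presence/absence CSV
#'
#' Accepts both the reduced dialect (`Gene`, `Annotation`, then one column
#' per genome, cells holding a locus tag or empty for absent) and the full
#' 14-column Roary header, whose extra bookkeeping columns are dropped.
#'
#' @param path CSV file path.
#' @return A [pa_matrix()].
#' @export
read_presence_absence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("empty presence/absence file: ", path,
                            call. = FALSE)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged presence/absence CSV at line ", bad, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"Gene" %in% names(df)) {
    stop("presence/absence CSV lacks a 'Gene' column", call. = FALSE)
  }
  ann <- if ("Annotation" %in% names(df)) df$Annotation else NULL
  genome_cols <- setdiff(names(df), c("Gene", "Annotation", ROARY_META_COLS))
  if (length(genome_cols) == 0) {
    stop("no genome columns found in ", path, call. = FALSE)
  }
  if (anyDuplicated(genome_cols)) {
    stop("duplicate genome columns: ",
         paste(unique(genome_cols[duplicated(genome_cols)]), collapse = ", "),
         call. = FALSE)
  }
  occ <- as.matrix(df[, genome_cols, drop = FALSE])
  rownames(occ) <- df$Gene
  occ[occ == ""] <- NA_character_
  pa_matrix(occ, ann)
}

#' Write a presence/absence matrix in the reduced Roary dialect
#'
#' @param pa A [pa_matrix()].
#' @param path Output CSV path.
#' @export
write_presence_absence <- function(pa, path) {
  stopifnot(inherits(pa, "pa_matrix"))
  occ <- pa$occupancy
  occ[is.na(occ)] <- ""
  df <- data.frame(Gene = rownames(occ),
                   Annotation = ifelse(is.na(pa$annotation), "",
                                       pa$annotation),
                   occ, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write an expression TSV (gene_id, count, length)
#'
#' TPM is recomputed on read, so the file stores only the primary data.
#'
#' @param path TSV path.
#' @return An [expression_table()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "numeric"))
  expression_table(df$gene_id, df$count, df$length)
}

#' @rdname read_expression_tsv
#' @param expr An [expression_table()].
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr[, c("gene_id", "count", "length")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gene models as GFF3
#'
#' CDS features with `ID`, `product`, `product_class`, `domains` (comma
#' separated), and `mobile_element_type` attributes in column 9; the
#' in-memory form is the flat gene-model data frame used across the package.
#'
#' @param path GFF3 path.
#' @param short_nt Passed to [flag_gene_models()].
#' @return Gene-model data frame with artifact flags.
#' @export
read_gene_gff3 <- function(path, short_nt = 300) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name) {
    if (!name %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[name]]
    if (methods::is(v, "List") || is.list(v)) {
      vapply(v, function(x) if (length(x) == 0) NA_character_ else
        paste(x, collapse = ","), character(1))
    } else {
      as.character(v)
    }
  }
  genes <- data.frame(
    gene_id = get_attr("ID"),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    product = get_attr("product"),
    product_class = get_attr("product_class"),
    domains = get_attr("domains"),
    mobile_element_type = get_attr("mobile_element_type"))
  genes$domains[is.na(genes$domains)] <- ""
  genes$product[is.na(genes$product)] <- ""
  flag_gene_models(genes, short_nt = short_nt)
}

#' @rdname read_gene_gff3
#' @param genes Gene-model data frame.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "linafunnel"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$product <- genes$product
  if ("product_class" %in% names(genes)) {
    S4Vectors::mcols(gr)$product_class <- genes$product_class
  }
  doms <- parse_domains(genes$domains)
  S4Vectors::mcols(gr)$domains <- methods::as(doms, "CharacterList")
  if ("mobile_element_type" %in% names(genes)) {
    S4Vectors::mcols(gr)$mobile_element_type <- genes$mobile_element_type
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome_fasta
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 80)
  invisible(path)
}

#' Read per-strain variant calls from VCF
#'
#' Accepts a single VCF or a directory of per-strain `*.vcf` files; the
#' strain id is the file name without extension. Variant kind is classified
#' from allele lengths. Records whose FILTER is neither `PASS` nor `.` are
#' dropped when `pass_only = TRUE`.
#'
#' @param path VCF file or directory.
#' @param pass_only Drop non-PASS records (default TRUE).
#' @return Data frame `strain`, `contig`, `pos`, `ref`, `alt`, `kind`.
#' @export
read_variants <- function(path, pass_only = TRUE) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.vcf$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop("no VCF files under ", path, call. = FALSE)
  out <- lapply(files, function(f) {
    v <- vcfR::read.vcfR(f, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) return(NULL)
    if (pass_only) {
      keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
      fix <- fix[keep, , drop = FALSE]
    }
    if (nrow(fix) == 0) return(NULL)
    data.frame(strain = sub("\\.vcf$", "", basename(f)),
               contig = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    stop("no variant records found under ", path, call. = FALSE)
  }
  out$kind <- variant_kind(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Write per-strain variant tables as minimal VCF 4.2 files
#'
#' One `<strain>.vcf` per strain under `dir`, carrying CHROM/POS/REF/ALT
#' with PASS filters; enough for the screen's re-analysis and for round
#' tripping through [read_variants()].
#'
#' @param variants Data frame `strain`, `contig`, `pos`, `ref`, `alt`.
#' @param dir Output directory (created if needed).
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return Invisibly, the written file paths.
#' @export
write_variant_vcfs <- function(variants, dir, contig_lengths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(variants, variants$strain), function(v) {
    f <- file.path(dir, paste0(v$strain[1], ".vcf"))
    header <- c("##fileformat=VCFv4.2",
                "##source=linafunnel",
                if (!is.null(contig_lengths)) {
                  sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths)
                },
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    v <- v[order(v$contig, v$pos), ]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    v$contig, v$pos, v$ref, v$alt)
    writeLines(c(header, body), f)
    f
  }, character(1))
  invisible(paths)
}

#' Read / write the strain phenotype table
#'
#' @param path TSV with columns `strain`, `phenotype` (`ina_lost`,
#'   `ina_reduced`, `wild_type`).
#' @return Data frame `strain`, `phenotype`.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("strain", "phenotype") %in% names(df)))
  bad <- setdiff(df$phenotype, c("ina_lost", "ina_reduced", "wild_type"))
  if (length(bad) > 0) {
    stop("unknown phenotype value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_phenotypes_tsv
#' @param phenotypes Data frame `strain`, `phenotype`.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write droplet-assay tables
#'
#' @param path CSV with columns `strain`, `replicate`, `dilution_factor`,
#'   `cfu_per_drop`, `temperature_c`, `n_drops`, `frozen`.
#' @return Validated assay data frame.
#' @export
read_assay_csv <- function(path) {
  validate_assay(utils::read.csv(path))
}

#' @rdname read_assay_csv
#' @param assay Assay data frame.
#' @export
write_assay_csv <- function(assay, path) {
  utils::write.csv(assay, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_assay_csv
#' @param spectrum A `freezing_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(spectrum, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a funnel bundle to disk in the pipeline's exchange formats
#'
#' Materialises a [gen_funnel_fixture()] bundle: presence/absence CSV,
#' expression TSV, GFF3 + FASTA, per-strain VCFs, phenotype TSV, assay CSVs,
#' and a `manifest.json` carrying the planted truth and generator
#' parameters.
#'
#' @param bundle A `funnel_bundle`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "funnel_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_presence_absence(bundle$pa, file.path(dir, "gene_presence_absence.csv"))
  write_expression_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_gene_gff3(bundle$genes, file.path(dir, "genes.gff3"))
  write_genome_fasta(bundle$genome, file.path(dir, "genome.fasta"))
  lens <- stats::setNames(Biostrings::width(bundle$genome),
                          names(bundle$genome))
  write_variant_vcfs(bundle$variants[, c("strain", "contig", "pos", "ref",
                                         "alt")],
                     file.path(dir, "vcf"), contig_lengths = lens)
  write_phenotypes_tsv(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  assay <- do.call(rbind, c(bundle$assays, list(bundle$control)))
  write_assay_csv(assay, file.path(dir, "assays.csv"))
  manifest <- list(
    generator = "linafunnel",
    config = unclass(bundle$config),
    note = paste("Background mutation loads are Poisson; the study states",
                 "only the mean."),
    truth = bundle$truth[c("unique_tags", "zero_ids", "core_expected",
                           "causal_gene_ids", "artifact_keys")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

default_pipeline_params <- function() {
  list(uniqueness = "all", tpm_threshold = 0, window_nt = 10000,
       artifact_mode = "both", min_strains = 2, include_reduced = FALSE,
       alpha = 0.05, combine = "weighted", short_nt = 300)
}

#' Run the full pipeline from files and assemble the report
#'
#' Reads every input, estimates a freezing spectrum and a detection call per
#' assayed strain, runs the candidate funnel, annotates and filters the
#' mutant variants, ranks genes by recurrence, intersects the funnel with
#' the screen, and returns one report object. All decision parameters are
#' echoed into the report for provenance.
#'
#' @param config Named list (or path to a YAML file) with input paths —
#'   `presence_absence`, `targets`, `expression`, `gff`, `fasta`, `vcf`
#'   (file or directory), `phenotypes`, optionally `assay` and
#'   `control_strain` — plus any of the decision parameters `uniqueness`,
#'   `tpm_threshold`, `window_nt`, `artifact_mode`, `min_strains`,
#'   `include_reduced`, `alpha`, `combine`, `short_nt`. Unknown keys are
#'   rejected.
#' @return A `pipeline_report` list: `stage_counts`, `stage_sets`,
#'   `ranked_genes`, `spectra`, `detection`, `removal_log`, `parameters`,
#'   `version`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("presence_absence", "targets", "expression", "gff", "fasta",
             "vcf", "phenotypes", "assay", "control_strain",
             names(default_pipeline_params()))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("presence_absence", "targets", "expression", "gff", "fasta",
                "vcf", "phenotypes")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("config lacks required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- utils::modifyList(default_pipeline_params(),
                              config[intersect(names(config),
                                               names(default_pipeline_params()))])

  pa <- read_presence_absence(config$presence_absence)
  expr <- read_expression_tsv(config$expression)
  genes <- read_gene_gff3(config$gff, short_nt = params$short_nt)
  genome <- read_genome_fasta(config$fasta)
  variants <- read_variants(config$vcf)
  phenotypes <- read_phenotypes_tsv(config$phenotypes)

  ann <- annotate_effect(variants, genes, genome)
  kept <- filter_artifacts(ann, genes, mode = params$artifact_mode)
  hits <- recurrently_hit_genes(kept, phenotypes,
                                min_strains = params$min_strains,
                                include_reduced = params$include_reduced)

  report_sets <- run_funnel(pa, config$targets, expr, genes,
                            screen_hits = hits$gene_id,
                            tpm_threshold = params$tpm_threshold,
                            uniqueness = params$uniqueness,
                            window_nt = params$window_nt)

  spectra <- NULL
  detection <- NULL
  if (!is.null(config$assay)) {
    assay <- read_assay_csv(config$assay)
    strains <- unique(assay$strain)
    ctrl_id <- config$control_strain
    spectra <- lapply(stats::setNames(nm = setdiff(strains, ctrl_id)),
                      function(s) {
                        spectrum_from_assay(assay[assay$strain == s, ],
                                            combine = params$combine)
                      })
    if (!is.null(ctrl_id) && ctrl_id %in% strains) {
      ctrl <- assay[assay$strain == ctrl_id, ]
      detection <- vapply(setdiff(strains, ctrl_id), function(s) {
        as.logical(ina_detectable(assay[assay$strain == s, ], ctrl,
                                  alpha = params$alpha))
      }, logical(1))
    }
  }

  structure(list(
    stage_counts = report_sets$stage_counts,
    stage_sets = report_sets$stage_sets,
    regions = report_sets$regions,
    ranked_genes = hits,
    spectra = spectra,
    detection = detection,
    removal_log = attr(kept, "removal_log"),
    parameters = params,
    version = as.character(utils::packageVersion("linafunnel"))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (linafunnel", x$version, ")\n")
  for (s in names(x$stage_counts)) {
    cat(sprintf("  %-24s %6d genes\n", s, x$stage_counts[[s]]))
  }
  if (nrow(x$ranked_genes) > 0) {
    cat("  recurrently hit genes:\n")
    print(x$ranked_genes[, c("gene_id", "n_strains")], row.names = FALSE)
  }
  if (!is.null(x$detection)) {
    cat("  INA detection:",
        paste(sprintf("%s=%s", names(x$detection), x$detection),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report` (or `candidate_report`).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$stage_counts <- as.list(out$stage_counts)
  if (!is.null(out$detection)) out$detection <- as.list(out$detection)
  out$spectra <- lapply(out$spectra, as.data.frame)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
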