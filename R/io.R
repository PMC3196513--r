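#' Read an evolution series from a passage-record CSV
#'
#' Expected header columns: `flask_index`, `final_od600` and/or
#' `final_cells`, and either `n0_cells` or the pair
#' `transfer_od` + `transfer_volume_L` (inoculum measured by OD). Optional:
#' `day`, `growth_rate_per_h`, `condition`, `mutagen` (true/false). One file
#' per replicate; empty cells are missing values.
#'
#' @param path CSV file path.
#' @param constants [calibration_constants()], used to convert `transfer_od`
#'   inocula to cell counts.
#' @return An [evolution_series()].
#' @export
read_passage_csv <- function(path, constants = calibration_constants()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- "flask_index"
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  mutagen <- if ("mutagen" %in% names(df)) {
    isTRUE(as.logical(df$mutagen[1]))
  } else FALSE
  condition <- if ("condition" %in% names(df)) df$condition[1] else "unspecified"

  if ("n0_cells" %in% names(df)) {
    n0 <- as.numeric(df$n0_cells)
  } else if (all(c("transfer_od", "transfer_volume_L") %in% names(df))) {
    conv <- if (mutagen) constants$cells_per_liter_per_od_mutagen
            else constants$cells_per_liter_per_od_no_mutagen
    n0 <- cells_from_od(as.numeric(df$transfer_od),
                        as.numeric(df$transfer_volume_L), conv)
  } else {
    stop("need either 'n0_cells' or 'transfer_od' + 'transfer_volume_L'")
  }
  bad <- which(is.na(n0))
  if (length(bad)) stop("malformed inoculum in row(s): ",
                        paste(bad, collapse = ", "))

  final_od <- if ("final_od600" %in% names(df)) as.numeric(df$final_od600)
              else NA_real_
  final_cells <- if ("final_cells" %in% names(df)) as.numeric(df$final_cells)
                 else NA_real_
  if (all(is.na(final_od)) && all(is.na(final_cells))) {
    stop("need 'final_od600' and/or 'final_cells'")
  }
  gr <- if ("growth_rate_per_h" %in% names(df)) as.numeric(df$growth_rate_per_h)
        else NA_real_
  evolution_series(flask_index = df$flask_index, n0 = n0,
                   final_od = final_od, final_cells = final_cells,
                   growth_rate = gr, condition = condition, mutagen = mutagen)
}

#' Write an evolution series as a passage-record CSV
#'
#' @param series An [evolution_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_passage_csv <- function(series, path) {
  df <- data.frame(flask_index = series$flask_index,
                   n0_cells = series$n0,
                   final_od600 = series$final_od,
                   final_cells = series$final_cells,
                   growth_rate_per_h = series$growth_rate,
                   condition = attr(series, "condition"),
                   mutagen = attr(series, "mutagen"))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a growth curve from CSV (columns time_h, od600)
#'
#' @param path CSV file path.
#' @return A [growth_curve()].
#' @export
read_growth_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "od600") %in% names(df))) {
    stop("growth-curve CSV needs columns time_h, od600")
  }
  growth_curve(df$time_h, df$od600)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings with the package's plain-character calling
#' convention; FASTA output is wrapped at 70 columns.
#'
#' @param path File path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ok <- grepl("^[ACGTN]*$", seqs)
  if (!all(ok)) {
    stop("invalid characters in record(s): ",
         paste(names(seqs)[!ok], collapse = ", "))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Reads are carried as plain characters (the alphabet includes the
#' ambiguity mark '.'); written qualities are a constant 'I'.
#'
#' @param path File path.
#' @return `read_fastq`: a `read_set` data.frame with columns `id`, `bases`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(data.frame(id = names(x), bases = as.character(x)),
            class = c("read_set", "data.frame"))
}

#' @rdname read_fastq
#' @param reads `read_set` data.frame or named character vector.
#' @export
write_fastq <- function(reads, path) {
  seqs <- if (is.data.frame(reads)) setNames(reads$bases, reads$id) else reads
  ok <- grepl("^[ACGTN.]*$", seqs)
  if (!all(ok)) {
    stop("invalid characters in record(s): ",
         paste(names(seqs)[!ok], collapse = ", "))
  }
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write SNP calls as a minimal VCF
#'
#' Emits a minimal valid VCFv4.2: header, then one line per call with 1-based
#' POS and the variant/reference counts in INFO (`VC`/`RC`).
#'
#' @param calls `snp_calls` data.frame from [call_snps()].
#' @param path Output path.
#' @param chrom Chromosome/contig name (default "ref").
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, chrom = "ref") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ccdtime-%s", as.character(packageVersion("ccdtime"))),
    "##INFO=<ID=VC,Number=1,Type=Integer,Description=\"Variant base count\">",
    "##INFO=<ID=RC,Number=1,Type=Integer,Description=\"Reference base count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- header
  if (nrow(calls) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVC=%d;RC=%d",
                              chrom, calls$position, calls$ref_base,
                              calls$called_base, calls$variant_count,
                              calls$reference_count))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF back into a calls table
#'
#' @param path VCF path (as written by [write_vcf()]).
#' @return A `snp_calls` data.frame.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(structure(data.frame(position = integer(), ref_base = character(),
                                called_base = character(),
                                variant_count = integer(),
                                reference_count = integer()),
                     class = c("snp_calls", "data.frame")))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, character(1), 8)
  vc <- as.integer(sub(".*VC=([0-9]+).*", "\\1", info))
  rc <- as.integer(sub(".*RC=([0-9]+).*", "\\1", info))
  structure(data.frame(
    position = as.integer(vapply(f, `[[`, character(1), 2)),
    ref_base = vapply(f, `[[`, character(1), 4),
    called_base = vapply(f, `[[`, character(1), 5),
    variant_count = vc, reference_count = rc
  ), class = c("snp_calls", "data.frame"))
}

#' Read an annotation track from a GFF-like TSV
#'
#' Columns: `name`, `start`, `end`, `strand`, `type` ("CDS" marks coding),
#' `product`; a product containing "conserved" or "predicted" marks an
#' unknown-function gene, and an optional `frame` column is honoured.
#'
#' @param path TSV path.
#' @return An [annotation_track()].
#' @export
read_annotation_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "strand", "type")
  if (!all(need %in% names(df))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  }
  product <- if ("product" %in% names(df)) df$product else ""
  annotation_track(
    name = df$name, start = df$start, end = df$end, strand = df$strand,
    coding = df$type == "CDS",
    frame = if ("frame" %in% names(df)) df$frame else 0L,
    unknown_function = grepl("conserved|predicted", product,
                             ignore.case = TRUE))
}

#' Read a simulator configuration from YAML
#'
#' @param path YAML file whose keys mirror the [sim_config()] arguments.
#' @param seed Optional seed overriding the file's.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 reads unsigned-exponent floats like 7.87e10 as strings
  vals <- lapply(vals, function(v) {
    if (is.character(v) && !anyNA(suppressWarnings(as.numeric(v)))) {
      as.numeric(v)
    } else v
  })
  if (!is.null(seed)) vals$seed <- seed
  do.call(sim_config, vals)
}

#' Run the demonstration pipeline
#'
#' Simulates one serial-passage evolution, writes its passage records, runs
#' the CCD calculus on the written file (exercising the read/write
#' round-trip), then runs the spike-in variant-calling analysis on a
#' synthetic genome, and writes a machine-readable run manifest. Every
#' artifact is reproducible from the seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param config A [sim_config()] (default: package defaults with `seed`).
#' @param genome_length Synthetic genome length for the variant-calling
#'   stage (default 20000).
#' @param n_spike,coverage Spike-in analysis parameters.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(out_dir, seed, config = NULL,
                         genome_length = 20000, n_spike = 60, coverage = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- sim_config(seed = seed)

  sim <- simulate_evolution(config)
  records_csv <- file.path(out_dir, "passage_records.csv")
  write_passage_csv(sim$series, records_csv)
  series <- read_passage_csv(records_csv)
  const <- calibration_constants(culture_volume = config$volume)
  ccd <- ccd_of_series(series, const)
  ccd_csv <- file.path(out_dir, "ccd_report.csv")
  write.csv(data.frame(flask_index = series$flask_index,
                       generations = ccd$per_flask_generations,
                       divisions = ccd$per_flask_divisions),
            ccd_csv, row.names = FALSE)

  set.seed(seed)
  genome <- generate_genome(genome_length)
  fa <- file.path(out_dir, "reference.fasta")
  write_fasta(c(ref = genome), fa)
  fn <- fn_rate_analysis(genome, n_spike = n_spike, coverage = coverage,
                         seed = seed + 1L)
  vcf <- file.path(out_dir, "calls.vcf")
  write_vcf(fn$calls, vcf)
  fn_json <- file.path(out_dir, "fn_report.json")
  jsonlite::write_json(list(per_type = fn$report$per_type,
                            overall = fn$report$overall),
                       fn_json, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    tool = "ccdtime",
    version = as.character(packageVersion("ccdtime")),
    seed = seed,
    inputs = list(sim_config = unclass(config),
                  genome_length = genome_length,
                  n_spike = n_spike, coverage = coverage),
    outputs = list(passage_records = records_csv, ccd_report = ccd_csv,
                   reference = fa, calls = vcf, fn_report = fn_json),
    results = list(flasks = nrow(series),
                   cumulative_generations = ccd$cumulative_generations,
                   ccd = ccd$ccd,
                   stabilization_flask = sim$stabilization_flask,
                   snp_detection = fn$report$per_type$fraction[
                     fn$report$per_type$type == "SNP"])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
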