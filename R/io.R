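#' Read genomes from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a genome table. Sequences are
#' normalized: uppercased and U converted to T. Under strict alphabet
#' handling any remaining non-ACGT character is a format error naming the
#' record; in lenient mode it is replaced by a seeded uniformly random base.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-ACGT characters (default TRUE).
#' @param seed Seed for lenient-mode base replacement.
#' @return A data.frame with columns `id`, `seq`, `description`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path, strict = TRUE, seed = 1L) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      description = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty header", call. = FALSE)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("FASTA record '%s' has an empty sequence",
                 ids[which(nchar(seqs) == 0L)[1]]), call. = FALSE)
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_seq(seqs[i], strict = strict, seed = child_seed(seed, i),
                  context = sprintf("record '%s'", ids[i]))
  }, character(1))
  data.frame(id = ids, seq = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write a genome table to FASTA
#'
#' @param genomes data.frame with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    desc <- if ("description" %in% names(genomes)) genomes$description[i] else ""
    header <- if (is.na(desc) || desc == "") genomes$id[i] else {
      paste(genomes$id[i], desc)
    }
    writeLines(paste0(">", header), con)
    s <- genomes$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a feature table
#'
#' Features are stranded intervals on a genome using 0-based half-open
#' coordinates internally (GFF3 emission converts to 1-based inclusive).
#'
#' @param genome_id,start,end,strand,kind Vectors (recycled to a common
#'   length) describing the intervals. `strand` must be "+" or "-".
#' @param score Numeric score or NA.
#' @param id Optional feature identifiers.
#' @param pvalue Optional p-values.
#' @return data.frame with one row per feature.
#' @export
features <- function(genome_id, start, end, strand = "+", kind = "region",
                     score = NA_real_, id = NA_character_,
                     pvalue = NA_real_) {
  if (length(genome_id) == 0L) {
    strand <- character(0); kind <- character(0)
    score <- numeric(0); id <- character(0); pvalue <- numeric(0)
  }
  df <- data.frame(genome_id = genome_id, start = as.integer(start),
                   end = as.integer(end), strand = strand, kind = kind,
                   score = as.numeric(score), id = as.character(id),
                   pvalue = as.numeric(pvalue), stringsAsFactors = FALSE)
  validate_features(df)
  df
}

empty_features <- function() {
  features(character(0), integer(0), integer(0), character(0), character(0),
           numeric(0), character(0), numeric(0))
}

validate_features <- function(df, genomes = NULL) {
  if (nrow(df) == 0L) return(invisible(df))
  stopifnot(all(df$strand %in% c("+", "-")))
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop("invalid feature interval: need 0 <= start < end", call. = FALSE)
  }
  if (!is.null(genomes)) {
    len <- stats::setNames(nchar(genomes$seq), genomes$id)
    if (!all(df$genome_id %in% names(len))) {
      stop("feature on unknown genome", call. = FALSE)
    }
    if (any(df$end > len[df$genome_id])) {
      stop("feature outside genome bounds", call. = FALSE)
    }
  }
  invisible(df)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to 1-based inclusive
#' GFF3 columns. Column 9 carries `ID`, `kind` and `pvalue` attributes;
#' column 3 is the feature kind. Writing then reading back with
#' [read_gff3()] reproduces the feature set.
#'
#' @param feats Feature table (see [features()]).
#' @param path Output path.
#' @param genomes Optional genome table used to validate bounds.
#' @export
write_gff3 <- function(feats, path, genomes = NULL) {
  validate_features(feats, genomes)
  if (nrow(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = feats$genome_id,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$source <- "sixsanno"
  S4Vectors::mcols(gr)$type <- feats$kind
  S4Vectors::mcols(gr)$score <- feats$score
  ids <- feats$id
  ids[is.na(ids)] <- paste0(feats$kind, "_", seq_len(nrow(feats)))[is.na(ids)]
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$kind <- feats$kind
  if (!all(is.na(feats$pvalue))) {
    S4Vectors::mcols(gr)$pvalue <- feats$pvalue
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' @param path Path to a GFF3 file.
#' @return Feature table with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  mc <- S4Vectors::mcols(gr)
  pv <- if ("pvalue" %in% names(mc)) as.numeric(as.character(mc$pvalue)) else NA_real_
  sc <- if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_
  features(genome_id = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           strand = as.character(GenomicRanges::strand(gr)),
           kind = if ("kind" %in% names(mc)) as.character(mc$kind) else as.character(mc$type),
           score = sc,
           id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
           pvalue = pv)
}

config_defaults <- function() {
  list(
    evalue_primary = 1e-30,
    evalue_cm_like = 1e-8,
    evalue_rescue = 0.1,
    evalue_anchor = 1e-40,
    anchor_window_nt = 2000L,
    merge_edit_distance = 10L,
    n_shuffles = 10L,
    fdr_fraction = 0.05,
    cre_upstream_nt = 100L,
    cre_pvalue = 1e-5,
    prna_length = 16L,
    prna_max_shift = 3L,
    seed = 1L
  )
}

#' Build a pipeline configuration
#'
#' Unspecified keys take the documented defaults: homology e-value tiers
#' 1e-30 (annotated references), 1e-8 (relaxed genome-wide pass), 0.1
#' (synteny rescue) and 1e-40 (anchor genes); a 2000-nt anchor window;
#' edit-distance 10 redundancy cutoff; 10 genome shuffles with a 5%
#' adaptive-threshold fraction; 100-nt upstream cre scan at p <= 1e-5;
#' 16-nt pRNAs shiftable by up to 3 nt.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_keys <- c("anchor_window_nt", "merge_edit_distance", "n_shuffles",
                "cre_upstream_nt", "prna_length", "prna_max_shift", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("evalue_primary", "evalue_cm_like", "evalue_rescue",
              "evalue_anchor", "fdr_fraction", "cre_pvalue")) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      stop(sprintf("config key '%s' must be a positive number", k),
           call. = FALSE)
    }
  }
  if (cfg$fdr_fraction > 1) stop("fdr_fraction must be in (0,1]", call. = FALSE)
  if (cfg$anchor_window_nt < 1L) stop("anchor_window_nt must be >= 1", call. = FALSE)
  if (cfg$prna_max_shift < 0L) stop("prna_max_shift must be >= 0", call. = FALSE)
  if (cfg$n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  if (cfg$prna_length < 1L) stop("prna_length must be >= 1", call. = FALSE)
  cfg
}

#' Load a pipeline configuration from a flat key-value (YAML) file
#'
#' @param path Path to a YAML file of scalar key: value pairs. An empty file
#'   yields all defaults.
#' @return Validated configuration list (see [pipeline_config()]).
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of key: value pairs",
                          call. = FALSE)
  cfg <- do.call(pipeline_config, raw)
  log_msg("INFO", "resolved config: ",
          paste(sprintf("%s=%s", names(cfg), unlist(cfg)), collapse = " "))
  cfg
}
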