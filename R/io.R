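#' Read a PLINK-style PED/MAP file pair
#'
#' Parses whitespace-separated PED/MAP text files into a [genotype_panel].
#' The MAP file supplies marker order and coordinates (chromosome, snp id,
#' genetic distance, 1-based position); the PED file carries six leading
#' fields (family, individual, father, mother, sex, phenotype) followed by
#' two allele columns per marker, with `"0"` denoting a missing allele.
#'
#' Alleles are recoded to minor-allele dosage, the minor allele being the
#' rarer allele in the pooled sample (ties broken lexicographically: the
#' alphabetically first allele becomes the major allele). Half-missing
#' genotypes (exactly one allele `"0"`) are treated as missing. The PED
#' phenotype dialect is fixed to `1` = control, `2` = case; any other code
#' (including `0`/`-9`) is rejected so labels can never silently flip.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_panel].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- read_tokens(map_path)
  if (any(lengths(map_lines) < 4L))
    stop("MAP parse error: line ",
         which(lengths(map_lines) < 4L)[1L], " has fewer than 4 fields")
  snps <- data.frame(
    snp_id = vapply(map_lines, `[`, "", 2L),
    chrom  = vapply(map_lines, `[`, "", 1L),
    pos    = as.integer(vapply(map_lines, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  m <- nrow(snps)

  ped_lines <- read_tokens(ped_path)
  want <- 6L + 2L * m
  ragged <- which(lengths(ped_lines) != want)
  if (length(ragged))
    stop("PED parse error: line ", ragged[1L], " has ",
         lengths(ped_lines)[ragged[1L]], " fields, expected ", want)
  ped <- do.call(rbind, ped_lines)
  pheno_code <- ped[, 6L]
  bad <- !pheno_code %in% c("1", "2")
  if (any(bad))
    stop("PED labeling error: phenotype code '", pheno_code[which(bad)[1L]],
         "' on line ", which(bad)[1L],
         " (expected 1 = control, 2 = case)")
  phenotype <- ifelse(pheno_code == "2", "case", "control")

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  rec <- recode_to_dosage(a1, a2, snps$snp_id)
  genotype_panel(rec$codes,
                 cbind(snps, rec$alleles),
                 phenotype, sample_id = ped[, 2L])
}

read_tokens <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(trimws(lines), "[ \t]+")
}

# allele-pair matrices -> dosage codes + major/minor orientation per SNP.
# Orientation uses pooled allele counts; lexicographic tie-break.
recode_to_dosage <- function(a1, a2, snp_ids) {
  m <- ncol(a1)
  codes <- matrix(NA_integer_, nrow(a1), m)
  major <- minor <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    half <- xor(x1 == "0", x2 == "0")
    x1[half] <- "0"; x2[half] <- "0"          # half-missing -> missing
    obs <- c(x1, x2); obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("multi-allelic error at SNP ", snp_ids[j], ": alleles ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L) alleles <- c("N", ".")
    if (length(alleles) == 1L) alleles <- c(alleles, ".")
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    # ties resolve to the sorted order: first allele is major
    ord <- if (cnt[2L] > cnt[1L]) 2:1 else 1:2
    major[j] <- alleles[ord[1L]]; minor[j] <- alleles[ord[2L]]
    ok <- x1 != "0" & x2 != "0"
    codes[ok, j] <- (x1[ok] == minor[j]) + (x2[ok] == minor[j])
  }
  list(codes = codes,
       alleles = data.frame(allele_major = major, allele_minor = minor,
                            stringsAsFactors = FALSE))
}

#' Write a panel as PED/MAP
#'
#' Inverse of [read_ped_map()]: dosage codes become allele pairs using the
#' panel's major/minor alleles, missing genotypes become `"0 0"`, and the
#' phenotype column is `1` for controls and `2` for cases.
#'
#' @param panel a [genotype_panel].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(panel, ped_path, map_path) {
  s <- panel$snps
  writeLines(sprintf("%s\t%s\t0\t%d", s$chrom, s$snp_id, s$pos), map_path)
  g <- panel$genotypes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    al <- vapply(seq_len(ncol(g)), function(j) {
      code <- g[i, j]
      if (is.na(code)) return("0 0")
      a <- c(rep(s$allele_major[j], 2L - code), rep(s$allele_minor[j], code))
      paste(a, collapse = " ")
    }, "")
    paste(c("FAM", panel$sample_id[i], "0", "0", "0",
            if (panel$phenotype[i] == "case") "2" else "1", al),
          collapse = " ")
  }, "")
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a CSV genotype table
#'
#' Dialect: a header row `sample_id, phenotype[, time, event]`, then one
#' column per SNP containing two-letter genotype strings (`"GG"`, `"GT"`) or
#' `"NA"` for a failed call. Optional `#meta` comment lines (as written by
#' [write_genotype_table()]) restore SNP chromosome/position metadata; when
#' absent, markers are placed at consecutive positions on chromosome `"."`.
#' Allele recoding follows the same minor-allele-dosage contract as
#' [read_ped_map()].
#'
#' @param csv_path path to the CSV file.
#' @return A [genotype_panel].
#' @export
read_genotype_table <- function(csv_path) {
  lines <- readLines(csv_path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                         colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  fixed <- intersect(c("sample_id", "phenotype", "time", "event"), names(tab))
  if (!all(c("sample_id", "phenotype") %in% fixed))
    stop("genotype table must start with sample_id and phenotype columns")
  snp_ids <- setdiff(names(tab), fixed)
  if (!length(snp_ids)) stop("no SNP columns found")
  if (!all(tab$phenotype %in% c("case", "control")))
    stop("labeling error: phenotype must be 'case' or 'control'")

  gs <- as.matrix(tab[, snp_ids, drop = FALSE])
  bad_fmt <- !(gs == "NA" | gs == "" | nchar(gs) == 2L)
  if (any(bad_fmt)) {
    idx <- which(bad_fmt, arr.ind = TRUE)[1L, ]
    stop("value error: malformed genotype '", gs[bad_fmt][1L], "' at row ",
         idx[1L], ", column ", snp_ids[idx[2L]])
  }
  miss <- gs == "NA" | gs == ""
  a1 <- substr(gs, 1L, 1L); a2 <- substr(gs, 2L, 2L)
  a1[miss] <- "0"; a2[miss] <- "0"
  rec <- recode_to_dosage(a1, a2, snp_ids)

  snps <- data.frame(snp_id = snp_ids, chrom = ".",
                     pos = seq_along(snp_ids), stringsAsFactors = FALSE)
  if (length(meta_lines)) {
    mm <- do.call(rbind, strsplit(meta_lines, "\t"))
    hit <- match(snps$snp_id, mm[, 2L])
    ok <- !is.na(hit)
    snps$chrom[ok] <- mm[hit[ok], 3L]
    snps$pos[ok] <- as.integer(mm[hit[ok], 4L])
  }
  time <- if ("time" %in% fixed) suppressWarnings(as.numeric(tab$time)) else NULL
  event <- if ("event" %in% fixed) suppressWarnings(as.integer(tab$event)) else NULL
  genotype_panel(rec$codes, cbind(snps, rec$alleles), tab$phenotype,
                 sample_id = tab$sample_id, time = time, event = event)
}

#' Write a panel as a CSV genotype table
#'
#' @param panel a [genotype_panel].
#' @param csv_path output path.
#' @return Invisibly, the path.
#' @export
write_genotype_table <- function(panel, csv_path) {
  s <- panel$snps
  g <- panel$genotypes
  gs <- matrix("NA", nrow(g), ncol(g))
  for (j in seq_len(ncol(g))) {
    code <- g[, j]
    ok <- !is.na(code)
    gs[ok, j] <- paste0(
      ifelse(code[ok] == 2L, s$allele_minor[j], s$allele_major[j]),
      ifelse(code[ok] == 0L, s$allele_major[j], s$allele_minor[j]))
  }
  colnames(gs) <- s$snp_id
  df <- data.frame(sample_id = panel$sample_id,
                   phenotype = as.character(panel$phenotype),
                   stringsAsFactors = FALSE)
  if (!is.null(panel$time)) {
    df$time <- panel$time
    df$event <- panel$event
  }
  df <- cbind(df, as.data.frame(gs, stringsAsFactors = FALSE))
  con <- file(csv_path, "w")
  on.exit(close(con))
  writeLines(sprintf("#meta\t%s\t%s\t%d", s$snp_id, s$chrom, s$pos), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(csv_path)
}

#' Write a report bundle
#'
#' Emits one TSV per analysis stage plus a single machine-readable JSON
#' bundle. Numeric columns are formatted to three decimals (matching the
#' precision conventional in association tables); re-running on identical
#' inputs yields byte-identical files.
#'
#' @param tables named list of data frames, one per analysis stage.
#' @param out_dir output directory (created if needed).
#' @param meta optional named list (seed, config hash, ...) stored in the
#'   JSON bundle.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, out_dir, meta = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    fmt <- tab
    for (k in seq_along(fmt))
      if (is.numeric(fmt[[k]]) && !is.integer(fmt[[k]]))
        fmt[[k]] <- ifelse(is.na(fmt[[k]]), "NA",
                           formatC(fmt[[k]], format = "f", digits = 3))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(fmt, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(out_dir, "report.json")
  bundle <- c(list(meta = meta), tables)
  jsonlite::write_json(bundle, jp, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(c(paths, jp))
}
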