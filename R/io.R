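# File formats: XYZ/PDB coordinate export, flat key-value configuration,
# plain-text ensemble archive.
#
# Conventions: coordinates in nm (converted to Angstrom for PDB), float64
# written at full precision, genomic coordinates 0-based half-open bp.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write nucleosome coordinates in XYZ format
#'
#' One record per nucleosome (element `N`), optionally followed by the
#' naked-DNA path vertices (element `D`). The comment line carries the
#' genomic length and the defect counts so a file is self-describing.
#'
#' @param fiber A `"fiber_conformation"`.
#' @param path Output file.
#' @param include_dna Also write naked-DNA vertices.
#' @return `path`, invisibly.
#' @export
write_conformation_xyz <- function(fiber, path, include_dna = FALSE) {
  n <- n_nucleosomes(fiber)
  nd <- if (include_dna) nrow(fiber$dna_path) else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(n + nd), con)
  writeLines(sprintf("chromatin fiber; nm; genomic_length_bp=%s; nucleosomes=%d; dna_vertices=%d",
                     format(fiber$genomic_length_bp), n, nd), con)
  for (i in seq_len(n))
    writeLines(paste("N", .fmt_num(fiber$centers[i, 1]),
                     .fmt_num(fiber$centers[i, 2]),
                     .fmt_num(fiber$centers[i, 3]),
                     fiber$genomic_index[i], sep = " "), con)
  if (nd > 0)
    for (i in seq_len(nd))
      writeLines(paste("D", .fmt_num(fiber$dna_path[i, 1]),
                       .fmt_num(fiber$dna_path[i, 2]),
                       .fmt_num(fiber$dna_path[i, 3]),
                       .fmt_num(fiber$dna_bp[i]), sep = " "), con)
  invisible(path)
}

#' Read an XYZ conformation file written by [write_conformation_xyz()]
#'
#' @param path File path.
#' @return List with `centers`, `genomic_index`, `dna_path`, `dna_bp`,
#'   `genomic_length_bp`.
#' @export
read_conformation_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("truncated XYZ file")
  n_total <- as.integer(lines[1])
  if (is.na(n_total)) stop("line 1: invalid atom count")
  glen <- suppressWarnings(as.numeric(
    sub(".*genomic_length_bp=([0-9.eE+-]+).*", "\\1", lines[2])))
  rec <- strsplit(lines[2 + seq_len(n_total)], " ", fixed = TRUE)
  el <- vapply(rec, `[`, character(1), 1)
  m <- t(vapply(rec, function(f) as.numeric(f[2:5]), numeric(4)))
  isn <- el == "N"
  list(centers = m[isn, 1:3, drop = FALSE],
       genomic_index = as.integer(m[isn, 4]),
       dna_path = m[!isn, 1:3, drop = FALSE],
       dna_bp = m[!isn, 4],
       genomic_length_bp = glen)
}

#' Write a fiber in PDB format
#'
#' Nucleosome centers as CA pseudo-atoms (residue numbers = genomic index,
#' 1-based), nm converted to Angstrom. Linker-histone skips are flagged by
#' occupancy 0.50, regular nucleosomes 1.00; naked-DNA vertices become
#' HETATM records of residue DNA.
#'
#' @param fiber A `"fiber_conformation"`.
#' @param path Output file.
#' @param include_dna Also write naked-DNA vertices.
#' @return `path`, invisibly.
#' @export
write_conformation_pdb <- function(fiber, path, include_dna = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 CHROMATIN FIBER %.1f KBP, COORDINATES NM*10 (ANGSTROM)",
                     fiber$genomic_length_bp / 1000), con)
  serial <- 0L
  for (i in seq_len(n_nucleosomes(fiber))) {
    serial <- serial + 1L
    occ <- if (fiber$lh_skip[i]) 0.50 else 1.00
    writeLines(sprintf(
      "ATOM  %5d  CA  NUC A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          NU",
      serial %% 100000L, (fiber$genomic_index[i] + 1L) %% 10000L,
      fiber$centers[i, 1] * 10, fiber$centers[i, 2] * 10,
      fiber$centers[i, 3] * 10, occ, 0), con)
  }
  if (include_dna && nrow(fiber$dna_path) > 0) {
    for (i in seq_len(nrow(fiber$dna_path))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "HETATM%5d  P   DNA B%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           P",
        serial %% 100000L, i %% 10000L,
        fiber$dna_path[i, 1] * 10, fiber$dna_path[i, 2] * 10,
        fiber$dna_path[i, 3] * 10, 1.0, 0), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write model/simulation parameters as a flat key-value file
#'
#' @param params An `"e2a_params"` or `"e2a_sim_config"`.
#' @param path Output file.
#' @param header Optional comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, header = NULL) {
  if (inherits(params, "e2a_sim_config")) {
    extra <- c(fiber_length_bp = params$fiber_length_bp,
               n_fibers = params$n_fibers, seed = params$seed,
               growth_max_retries = params$growth_max_retries,
               mc_moves_per_site = params$mc_moves_per_site)
    params <- params$params
  } else extra <- NULL
  stopifnot(inherits(params, "e2a_params"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  fields <- params[!vapply(params, is.function, logical(1))]
  for (nm in names(fields))
    writeLines(sprintf("%s = %s", nm,
                       paste(.fmt_num(as.numeric(fields[[nm]])),
                             collapse = " ")), con)
  if (!is.null(extra))
    for (nm in names(extra))
      writeLines(sprintf("%s = %s", nm, .fmt_num(extra[nm])), con)
  invisible(path)
}

#' Read a flat key-value parameter file
#'
#' @param path File written by [write_config()] (or hand-written in the
#'   same `key = value` format; `#` starts a comment).
#' @return An `"e2a_params"` object; keys that describe the run
#'   (`fiber_length_bp`, `n_fibers`, `seed`, ...) are returned in the
#'   attribute `run`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- lapply(kv, function(f)
    as.numeric(strsplit(trimws(paste(f[-1], collapse = "=")), " +")[[1]]))
  names(vals) <- keys
  run_keys <- c("fiber_length_bp", "n_fibers", "seed", "growth_max_retries",
                "mc_moves_per_site")
  run <- vals[names(vals) %in% run_keys]
  vals <- vals[!names(vals) %in% c(run_keys, "linker_bp")]
  args <- vals[names(vals) %in% names(formals(e2a_params))]
  p <- do.call(e2a_params, args)
  attr(p, "run") <- run
  p
}

#' Write a fiber ensemble to a portable text archive
#'
#' Single-file, sectioned, versioned plain-text container: a header with
#' schema version, seed and configuration hash, the flat parameter block,
#' and per-fiber sections with element angles and nucleosome/DNA
#' coordinates at full double precision. Reading back reproduces the
#' ensemble losslessly.
#'
#' @param ensemble A `"fiber_ensemble"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_archive <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fiber_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("!e2a_ensemble_archive")
  w("schema_version\t1")
  w("seed\t%d", ensemble$seed)
  w("config_hash\t%s", ensemble$config_hash)
  w("n_fibers\t%d", length(ensemble$fibers))
  w("fiber_length_bp\t%s", .fmt_num(ensemble$config$fiber_length_bp))
  w("[params]")
  p <- ensemble$config$params
  for (nm in names(p))
    w("%s\t%s", nm, paste(.fmt_num(as.numeric(p[[nm]])), collapse = "\t"))
  for (k in seq_along(ensemble$fibers)) {
    f <- ensemble$fibers[[k]]
    w("[fiber %d]", k)
    w("sub_seed\t%d", ensemble$sub_seeds[k])
    w("defect_mask\t%s", paste(unclass(f$defect_mask), collapse = ","))
    el <- f$elements
    w("[elements %d]", length(el$el_type))
    for (i in seq_along(el$el_type))
      w("%d\t%d\t%d\t%s\t%s\t%s\t%s", el$el_type[i], el$el_sub[i],
        el$el_gidx[i], .fmt_num(el$el_len[i]), .fmt_num(el$el_a1[i]),
        .fmt_num(el$el_a2[i]), .fmt_num(el$el_bp[i]))
  }
  w("[end]")
  invisible(path)
}

#' Read a fiber ensemble archive
#'
#' Rebuilds every fiber deterministically from the archived element angles
#' through the same geometry engine used for growth; the stored schema
#' version is checked.
#'
#' @param path Archive written by [write_ensemble_archive()].
#' @return A `"fiber_ensemble"`.
#' @export
read_ensemble_archive <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "!e2a_ensemble_archive")
    stop("not an ensemble archive (missing magic line)")
  get_kv <- function(key, upto) {
    ln <- grep(paste0("^", key, "\t"), lines[seq_len(upto)], value = TRUE)
    if (!length(ln)) stop("archive missing field: ", key)
    strsplit(ln[1], "\t", fixed = TRUE)[[1]][-1]
  }
  pstart <- match("[params]", lines)
  ver <- as.integer(get_kv("schema_version", pstart))
  if (!identical(ver, 1L))
    stop("unsupported archive schema version: ", ver)
  seed <- as.integer(get_kv("seed", pstart))
  n_fib <- as.integer(get_kv("n_fibers", pstart))
  flen <- as.numeric(get_kv("fiber_length_bp", pstart))
  fib_marks <- grep("^\\[fiber ", lines)
  plines <- lines[(pstart + 1):(fib_marks[1] - 1)]
  kv <- strsplit(plines, "\t", fixed = TRUE)
  pv <- lapply(kv, function(f) as.numeric(f[-1]))
  names(pv) <- vapply(kv, `[`, character(1), 1)
  pv <- pv[!names(pv) %in% "linker_bp"]
  args <- pv[names(pv) %in% names(formals(e2a_params))]
  params <- do.call(e2a_params, args)
  ends <- c(fib_marks[-1], match("[end]", lines))
  fibers <- vector("list", n_fib)
  sub_seeds <- integer(n_fib)
  for (k in seq_len(n_fib)) {
    blk <- lines[fib_marks[k]:(ends[k] - 1)]
    sub_seeds[k] <- as.integer(strsplit(
      grep("^sub_seed\t", blk, value = TRUE), "\t")[[1]][2])
    mask_line <- strsplit(grep("^defect_mask\t", blk, value = TRUE),
                          "\t")[[1]][2]
    mask <- defect_mask(strsplit(mask_line, ",", fixed = TRUE)[[1]], params)
    estart <- grep("^\\[elements ", blk)
    erows <- strsplit(blk[(estart + 1):length(blk)], "\t", fixed = TRUE)
    em <- t(vapply(erows, as.numeric, numeric(7)))
    chain <- list(el_type = as.integer(em[, 1]), el_sub = as.integer(em[, 2]),
                  el_gidx = as.integer(em[, 3]), el_len = em[, 4],
                  el_a1 = em[, 5], el_a2 = em[, 6], el_bp = em[, 7])
    rebuilt <- cpp_rebuild(chain, .cpp_par(params))
    f <- .fiber_from_chain(rebuilt, params, flen, seed = sub_seeds[k])
    f$defect_mask <- mask
    fibers[[k]] <- f
  }
  cfg <- sim_config(params, fiber_length_bp = flen, n_fibers = n_fib,
                    seed = seed)
  ens <- list(fibers = fibers, config = cfg, seed = seed,
              sub_seeds = sub_seeds, config_hash = config_hash(cfg))
  class(ens) <- "fiber_ensemble"
  ens
}
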