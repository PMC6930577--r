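# File formats: multi-frame XYZ, PDB (via bio3d), TSV constraint dialects,
# flat key=value run configuration, topology tables and run manifests.

#' Write / read multi-frame XYZ
#'
#' Standard XYZ: atom count line, comment line (`t= <ps>` for trajectory
#' frames), then `element x y z` rows (A, %.6f).
#'
#' @param coords a coordinate matrix, a `conformation`, or a list of
#'   either.
#' @param path file path.
#' @param elements element symbols, one per atom.
#' @param times optional per-frame time stamps, ps.
#' @return `path` invisibly; `read_xyz()` returns
#'   `list(coords, elements, times)`.
#' @export
write_xyz <- function(coords, path, elements, times = NULL) {
  if (inherits(coords, "conformation") || is.matrix(coords)) {
    coords <- list(coords)
  }
  coords <- lapply(coords, as_xyz)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(coords)) {
    x <- coords[[f]]
    writeLines(as.character(nrow(x)), con)
    writeLines(if (is.null(times)) paste("frame", f) else
      sprintf("t= %.6f", times[f]), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", elements,
                       x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  coords <- list(); times <- numeric(0); elements <- NULL
  pos <- 1
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop(path, ":", pos, ": expected atom count, got '",
                       lines[pos], "'")
    comment <- lines[pos + 1]
    rows <- lines[(pos + 2):(pos + 1 + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad)) stop(path, ":", pos + 1 + bad[1], ": malformed XYZ row")
    el <- vapply(parts, `[`, character(1), 1)
    x <- suppressWarnings(
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
    if (anyNA(x)) stop(path, ": non-numeric coordinate near line ", pos + 2)
    if (is.null(elements)) elements <- el
    coords[[length(coords) + 1]] <- x
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    pos <- pos + 2 + n
  }
  list(coords = coords, elements = elements, times = times)
}

#' Write / read a single-frame PDB
#'
#' Thin wrappers over bio3d; coordinates are interpreted in A and atom
#' order is preserved.
#'
#' @param conf `conformation` or coordinate matrix.
#' @param path file path.
#' @param elements element symbols.
#' @return `path` invisibly; `read_pdb_coords()` returns
#'   `list(coords, elements)`.
#' @export
write_pdb <- function(conf, path, elements) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB output")
  }
  x <- as_xyz(conf)
  bio3d::write.pdb(file = path, xyz = as.vector(t(x)),
                   elety = paste0(elements, seq_along(elements)),
                   resno = rep(1, nrow(x)), resid = rep("MOL", nrow(x)))
  invisible(path)
}

#' @rdname write_pdb
#' @export
read_pdb_coords <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required for PDB input")
  }
  pdb <- bio3d::read.pdb(path)
  x <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(coords = x, elements = gsub("[0-9]", "", pdb$atom$elety))
}

col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

write_tsv_commented <- function(df, path, comment) {
  writeLines(paste0("# ", comment), path)
  suppressMessages(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob)) {
    stop(path, ":", prob$row[1] + 1, ": malformed ", what, " record (",
         prob$expected[1], ")")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) warning(path, ": empty ", what, " table")
  df
}

#' Write constraint tables
#'
#' Serialises the native tidy dialects to TSV with a `#` comment header.
#'
#' @param tables list with any of `rdc`, `noe`, `j` tibbles.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_constraint_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(tables$rdc)) {
    paths["rdc"] <- file.path(dir, "rdc.tsv")
    write_tsv_commented(tables$rdc, paths["rdc"],
                        "mdoc RDC table: id class i j h2 h3 d_exp[Hz] error[Hz] delta[Hz] d_stat[Hz]")
  }
  if (!is.null(tables$noe)) {
    paths["noe"] <- file.path(dir, "noe.tsv")
    write_tsv_commented(tables$noe, paths["noe"],
                        "mdoc NOE table: id i j h2 h3 target[A] error[A] delta[A]")
  }
  if (!is.null(tables$j)) {
    paths["j"] <- file.path(dir, "j.tsv")
    write_tsv_commented(tables$j, paths["j"],
                        "mdoc 3J table: id i j k l j_exp[Hz] error[Hz] delta[Hz] chi xi param_set")
  }
  if (!is.null(tables$manifest)) {
    paths["manifest"] <- file.path(dir, "manifest.tsv")
    write_tsv_commented(tables$manifest, paths["manifest"], "mdoc synth manifest")
  }
  invisible(paths)
}

#' Read constraint tables
#'
#' Strict readers for the TSV dialects; malformed lines and out-of-range
#' atom references raise errors with file and line context.
#'
#' @param rdc,noe,j file paths (any may be `NULL`).
#' @param system optional `molecular_system` for atom-index validation.
#' @return list of class `constraint_set` with the parsed tibbles.
#' @export
read_constraint_tables <- function(rdc = NULL, noe = NULL, j = NULL,
                                   system = NULL) {
  out <- list()
  if (!is.null(rdc)) {
    df <- read_tsv_strict(rdc, c("id", "class", "i", "j", "d_exp", "error"),
                          "RDC")
    df$h2 <- col_or(df, "h2", NA_integer_)
    df$h3 <- col_or(df, "h3", NA_integer_)
    df$delta <- col_or(df, "delta", 0.5)
    df$d_stat <- col_or(df, "d_stat", NA_real_)
    out$rdc <- rdc_table(df$id, df$class, df$i, df$j, df$h2, df$h3,
                         df$d_exp, df$error, df$delta, df$d_stat)
  }
  if (!is.null(noe)) {
    df <- read_tsv_strict(noe, c("id", "i", "j", "target", "error"), "NOE")
    df$h2 <- col_or(df, "h2", NA_integer_)
    df$h3 <- col_or(df, "h3", NA_integer_)
    df$delta <- col_or(df, "delta", 0.25)
    out$noe <- noe_table(df$id, df$i, df$j, df$h2, df$h3, df$target,
                         df$error, df$delta)
  }
  if (!is.null(j)) {
    df <- read_tsv_strict(j, c("id", "i", "j", "k", "l", "j_exp", "error"),
                          "3J")
    df$delta <- col_or(df, "delta", 0.5)
    df$chi <- col_or(df, "chi", "")
    df$xi <- col_or(df, "xi", "")
    df$param_set <- col_or(df, "param_set", "hla2")
    df$chi[is.na(df$chi)] <- ""
    df$xi[is.na(df$xi)] <- ""
    out$j <- j_table(df$id, df$i, df$j, df$k, df$l, df$j_exp, df$error,
                     df$delta, df$chi, df$xi, df$param_set)
  }
  if (!is.null(system)) {
    n <- nrow(system$atoms)
    for (nm in names(out)) {
      ix <- unlist(out[[nm]][intersect(names(out[[nm]]),
                                       c("i", "j", "k", "l", "h2", "h3"))])
      ix <- ix[!is.na(ix)]
      if (any(ix < 1 | ix > n)) {
        stop(nm, " table references unknown atom index ",
             paste(unique(ix[ix < 1 | ix > n]), collapse = ", "))
      }
    }
  }
  structure(out, class = "constraint_set")
}

#' Per-class constraint counts
#'
#' @param x a `constraint_set` (or plain list of constraint tibbles).
#' @return named integer vector: one-bond RDC, long-range RDC, NOE, 3J.
#' @export
constraint_counts <- function(x) {
  rdc <- x$rdc
  c(oneD = if (is.null(rdc)) 0L else sum(rdc$class %in% c("one-bond", "methyl")),
    nD = if (is.null(rdc)) 0L else sum(rdc$class == "long-range"),
    noe = if (is.null(x$noe)) 0L else nrow(x$noe),
    j = if (is.null(x$j)) 0L else nrow(x$j))
}

#' @export
print.constraint_set <- function(x, ...) {
  cc <- constraint_counts(x)
  cat("<constraint_set>", cc["oneD"], "one-bond RDC,", cc["nD"],
      "long-range RDC,", cc["noe"], "NOE,", cc["j"], "3J\n")
  invisible(x)
}

#' Write / read the flat run-configuration file
#'
#' One `key = value` pair per line, keys exactly the [mdoc_config()]
#' fields.
#'
#' @param config an `mdoc_config`.
#' @param path file path.
#' @return `path` invisibly; `read_mdoc_config()` returns an `mdoc_config`.
#' @export
write_mdoc_config <- function(config, path) {
  keys <- setdiff(names(config), "record_log")
  writeLines(c("# mdoc run configuration",
               sprintf("%s = %s", keys,
                       vapply(config[keys], format, character(1)))), path)
  invisible(path)
}

#' @rdname write_mdoc_config
#' @export
read_mdoc_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop(path, ": malformed config line: ", lines[bad[1]])
  vals <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                          vapply(kv, `[`, character(1), 1))
  known <- names(formals(mdoc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop(path, ": unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(mdoc_config, vals)
}

#' Topology table I/O
#'
#' A single TSV holding atoms and bonded terms distinguished by a `record`
#' column (`atom`, `bond`, `angle`, `torsion`); unused fields are empty.
#'
#' @param system a `molecular_system`.
#' @param path file path.
#' @return `path` invisibly; `read_topology()` returns a
#'   `molecular_system` built with [build_system()].
#' @export
write_topology <- function(system, path) {
  a <- dplyr::mutate(system$atoms, record = "atom", .before = 1)
  # bond force constant is written as `kb` so `k` can stay an atom index
  b <- dplyr::mutate(dplyr::rename(system$bonds, kb = "k"),
                     record = "bond", .before = 1)
  g <- dplyr::mutate(system$angles, record = "angle", .before = 1)
  t_ <- dplyr::mutate(system$torsions, record = "torsion", .before = 1)
  df <- dplyr::bind_rows(a, b, g, t_)
  write_tsv_commented(df, path, "mdoc topology: atoms + bonded terms")
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- read_tsv_strict(path, "record", "topology")
  pick <- function(rec, cols) {
    d <- df[df$record == rec, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    miss <- setdiff(cols, names(d))
    if (length(miss)) stop(path, ": ", rec, " records lack column(s): ",
                           paste(miss, collapse = ", "))
    d[cols]
  }
  bonds <- pick("bond", c("i", "j", "r0", "kb"))
  if (!is.null(bonds)) bonds <- dplyr::rename(bonds, k = "kb")
  build_system(list(
    atoms = pick("atom", c("name", "element", "mass", "charge", "sigma",
                           "epsilon")),
    bonds = bonds,
    angles = pick("angle", c("i", "j", "k", "theta0", "kth")),
    torsions = pick("torsion", c("i", "j", "k", "l", "n", "phase", "v"))))
}

#' Run manifest
#'
#' Records the configuration snapshot, input-file MD5 digests, seed,
#' package version and wall-clock start time of a run.
#'
#' @param config an `mdoc_config`.
#' @param inputs named character vector of input file paths.
#' @return a tibble; write it with `readr::write_tsv()`.
#' @export
run_manifest <- function(config, inputs = character(0)) {
  digests <- if (length(inputs)) unname(tools::md5sum(inputs)) else character(0)
  tibble::tibble(
    key = c("started", "version", "seed",
            paste0("config.", setdiff(names(config), "record_log")),
            if (length(inputs)) paste0("md5.", names(inputs))),
    value = c(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              as.character(utils::packageVersion("mdoc")),
              as.character(config$seed),
              vapply(config[setdiff(names(config), "record_log")], format,
                     character(1)),
              digests))
}
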