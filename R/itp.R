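#' Export a parameter selection as GROMACS topology fragments
#'
#' Emits `[atomtypes]` entries for the selected Mg2+ set and its Cl-
#' reference partner, and explicit `[nonbond_params]` override lines
#' (function type 1, sigma/epsilon convention, full double precision) for
#' the Mg-Cl pair and for Mg against every requested RNA atom type.  The
#' overrides are required because scaled combination rules cannot be
#' expressed through GROMACS' global combination-rule setting.
#'
#' @param reg A `Registry`.
#' @param variant Mg set label (`"microMg"` or `"nanoMg"`).
#' @param water Water model name.
#' @param rna_types Optional data frame with columns `type`, `sigma`, `eps`
#'   (defaults to the registry's RNA atom-type table) for the RNA overrides;
#'   `NULL` suppresses RNA lines.
#' @param file Optional path; when given the document is also written there.
#' @param use_reconstructed Reconstruct full-precision Mg `sigma_ii` from
#'   `2 sigma_io - sigma_OO` for the pair lines (default).
#' @return Character vector of topology lines, invisibly when `file` is set.
#' @export
#' @examples
#' reg <- load_registry()
#' head(export_itp(reg, "microMg", "SPC/E"))
export_itp <- function(reg, variant, water, rna_types = reg$rna_atomtypes,
                       file = NULL, use_reconstructed = TRUE) {
  water <- .match_water(reg, water)
  mg <- ion_set(reg, variant, water)
  cl <- cl_set(reg, water)
  w <- reg$water_models[[water]]
  part <- mg
  if (use_reconstructed) part$sigma_ii <- reconstructed_ii(mg, w)$sigma_ii
  num <- function(x) sprintf("%.17g", x) # 17 significant digits round-trip doubles exactly
  lines <- c(
    sprintf("; %s Mg2+ parameters for %s water", variant, water),
    "[ atomtypes ]",
    ";name  at.num  mass      charge   ptype  sigma            epsilon",
    sprintf("MG     12      24.30500  2.00000  A      %s  %s",
            num(mg$sigma_ii), num(mg$eps_ii)),
    sprintf("CL     17      35.45300 -1.00000  A      %s  %s",
            num(cl$sigma_ii), num(cl$eps_ii)),
    "",
    "[ nonbond_params ]",
    ";i    j      func  sigma            epsilon"
  )
  p_cl <- scaled_lb(part, cl, scaling_for(reg, variant, water, "Cl"))
  lines <- c(lines, sprintf("MG    CL     1     %s  %s",
                            num(p_cl$sigma_pair), num(p_cl$eps_pair)))
  if (!is.null(rna_types)) {
    if (!all(c("type", "sigma", "eps") %in% names(rna_types)))
      stop("rna_types needs columns type, sigma, eps", call. = FALSE)
    s_rna <- scaling_for(reg, variant, water, "RNA")
    for (i in seq_len(nrow(rna_types))) {
      p <- scaled_lb(mg, rna_types[i, ], s_rna)
      lines <- c(lines, sprintf("MG    %-6s 1     %s  %s",
                                rna_types$type[i], num(p$sigma_pair),
                                num(p$eps_pair)))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse GROMACS topology fragments written by [export_itp()]
#'
#' @param x Character vector of topology lines, or a file path.
#' @return List with data frames `atomtypes` (name, charge, sigma, epsilon)
#'   and `nonbond_params` (i, j, func, sigma, epsilon).  Numeric values
#'   round-trip bit-exactly through [export_itp()].
#' @export
parse_itp <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- readLines(x)
  x <- sub(";.*$", "", x)
  x <- trimws(x)
  section <- NA_character_
  at <- list(); nb <- list()
  for (line in x) {
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^\\[\\s*(\\S+)\\s*\\]$", line))[[1]]
    if (length(m)) { section <- m[2]; next }
    f <- strsplit(line, "\\s+")[[1]]
    if (identical(section, "atomtypes")) {
      at[[length(at) + 1L]] <- data.frame(
        name = f[1], charge = as.numeric(f[4]),
        sigma = as.numeric(f[6]), epsilon = as.numeric(f[7]),
        stringsAsFactors = FALSE)
    } else if (identical(section, "nonbond_params")) {
      nb[[length(nb) + 1L]] <- data.frame(
        i = f[1], j = f[2], func = as.integer(f[3]),
        sigma = as.numeric(f[4]), epsilon = as.numeric(f[5]),
        stringsAsFactors = FALSE)
    }
  }
  list(atomtypes = if (length(at)) do.call(rbind, at) else NULL,
       nonbond_params = if (length(nb)) do.call(rbind, nb) else NULL)
}
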