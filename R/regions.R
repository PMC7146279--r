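#' Define lip and subdomain regions on a chain
#'
#' A `region_set` names the four residue-range partitions the hinge analysis
#' needs: the two lips flanking the active-site cleft (whose Calpha centers
#' define the mouth-opening distance) and the two subdomains (whose relative
#' rigid rotation defines the hinge-bending angle). Residue numbers are
#' author (PDB) numbering; ranges are inclusive on both ends.
#'
#' @param chain_id chain identifier the regions live on (no implicit
#'   first-chain guess is ever made).
#' @param lip1,lip2,subdomain1,subdomain2 each a list of inclusive
#'   `c(start, end)` residue-number ranges (a single range may be given as a
#'   bare two-vector). Every lip1 range must fall inside the union of
#'   subdomain1 ranges, and likewise lip2 within subdomain2.
#' @return An object of class `region_set`.
#' @seealso [region_preset()] for the shipped ACE / ACE2 definitions.
#' @export
region_set <- function(chain_id, lip1, lip2, subdomain1, subdomain2) {
  norm <- function(r, nm) {
    if (is.numeric(r) && length(r) == 2L) r <- list(r)
    if (!is.list(r) || length(r) == 0L)
      hs_stop("invalid_region", "region '%s' must be a non-empty list of ranges", nm)
    out <- lapply(r, function(x) {
      x <- as.integer(x)
      if (length(x) != 2L || x[1] > x[2])
        hs_stop("invalid_region", "malformed range in region '%s'", nm)
      x
    })
    # non-overlap within one region
    ord <- order(vapply(out, `[`, integer(1), 1L))
    out <- out[ord]
    if (length(out) > 1L) {
      for (i in 2:length(out)) {
        if (out[[i]][1] <= out[[i - 1]][2])
          hs_stop("invalid_region", "overlapping ranges in region '%s'", nm)
      }
    }
    out
  }
  lip1 <- norm(lip1, "lip1"); lip2 <- norm(lip2, "lip2")
  subdomain1 <- norm(subdomain1, "subdomain1")
  subdomain2 <- norm(subdomain2, "subdomain2")
  contained <- function(inner, outer) {
    all(vapply(inner, function(r) {
      any(vapply(outer, function(o) r[1] >= o[1] && r[2] <= o[2], logical(1)))
    }, logical(1)))
  }
  if (!contained(lip1, subdomain1))
    hs_stop("invalid_region", "lip1 ranges are not contained in subdomain1")
  if (!contained(lip2, subdomain2))
    hs_stop("invalid_region", "lip2 ranges are not contained in subdomain2")
  structure(list(chain_id = as.character(chain_id), lip1 = lip1, lip2 = lip2,
                 subdomain1 = subdomain1, subdomain2 = subdomain2),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  fmt <- function(r) paste(vapply(r, function(v) sprintf("%d-%d", v[1], v[2]),
                                  character(1)), collapse = ", ")
  cat(sprintf("<region_set> chain %s\n  lip1: %s\n  lip2: %s\n  subdomain1: %s\n  subdomain2: %s\n",
              x$chain_id, fmt(x$lip1), fmt(x$lip2), fmt(x$subdomain1),
              fmt(x$subdomain2)))
  invisible(x)
}

#' Load a shipped or on-disk region definition
#'
#' Two presets are shipped as YAML under `inst/extdata/regions/`:
#' \describe{
#'   \item{`"sace_cdomain"`}{somatic ACE C-domain in the author numbering of
#'     PDB entry 4APH. Lip I: 73-100, 297-304, 348-354, 370-379 on
#'     subdomain I (40-122, 297-437, 551-583); lip II: 128-150, 160-173,
#'     284-293 on subdomain II (123-296, 438-550, 584-625).}
#'   \item{`"ace2"`}{ACE2 in the numbering of PDB entries 1R4L/1R42.
#'     Lip I: 54-81, 289-296, 340-346, 361-370; lip II: 109-131, 143-156,
#'     267-276. The subdomain boundaries are package-defined by homology
#'     with the ACE split (crystallographic publications report the lips
#'     but not a subdomain partition in ACE2 numbering).}
#' }
#'
#' @param name preset name (`"sace_cdomain"` or `"ace2"`) or a path to a
#'   YAML file with keys `chain_id`, `lip1`, `lip2`, `subdomain1`,
#'   `subdomain2`, each region a list of `[start, end]` pairs.
#' @return a [region_set()].
#' @export
region_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "regions", paste0(name, ".yaml"),
                package = "hingescope")
  if (!nzchar(path) || !file.exists(path))
    hs_stop("unknown_preset", "no region preset or file named '%s'", name)
  spec <- yaml::read_yaml(path)
  for (k in c("chain_id", "lip1", "lip2", "subdomain1", "subdomain2"))
    if (is.null(spec[[k]]))
      hs_stop("invalid_region", "region file '%s' lacks key '%s'", path, k)
  region_set(spec$chain_id, spec$lip1, spec$lip2, spec$subdomain1,
             spec$subdomain2)
}

#' Write a region_set to a YAML file
#' @param regions a [region_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  out <- list(chain_id = regions$chain_id,
              lip1 = lapply(regions$lip1, as.integer),
              lip2 = lapply(regions$lip2, as.integer),
              subdomain1 = lapply(regions$subdomain1, as.integer),
              subdomain2 = lapply(regions$subdomain2, as.integer))
  yaml::write_yaml(out, path)
  invisible(path)
}
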