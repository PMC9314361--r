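# Network config schema (YAML): species list, reactions given as named
# reactant counts plus either a mass-action rate, a typed structured
# propensity, or a small `expr:` rate expression (arithmetic, max(), and
# hill(x, K0, K1, H)); displacements as named count changes or a
# partition-kernel description; and the output species name.

named_counts <- function(v, species) {
  nz <- which(v != 0)
  if (length(nz) == 0) return(NULL)
  as.list(stats::setNames(v[nz], species[nz]))
}

counts_vector <- function(lst, species) {
  v <- rep(0, length(species))
  if (is.null(lst)) return(v)
  idx <- match(names(lst), species)
  if (anyNA(idx)) stop("unknown species in config: ",
                       paste(names(lst)[is.na(idx)], collapse = ", "))
  v[idx] <- unlist(lst)
  v
}

propensity_to_list <- function(p, species) {
  switch(p$type,
    mass_action = list(type = "mass_action", rate = p$rate),
    const = list(type = "const", value = p$value),
    affine = list(type = "affine", const = p$const,
                  coef = named_counts(p$coef, species)),
    hill_repression = list(type = "hill_repression", K0 = p$K0, K1 = p$K1,
                           H = p$H, species = species[p$species]),
    hill_feedback = list(type = "hill_feedback", kfb = p$kfb, mu = p$mu,
                         species = species[p$species]),
    prop_feedback = list(type = "prop_feedback", kfb = p$kfb, mu = p$mu,
                         species = species[p$species]),
    custom = {
      ex <- attr(p$fn, "expr_text")
      if (is.null(ex)) stop("custom propensity closures cannot be serialised")
      list(type = "expr", expr = ex)
    })
}

propensity_from_list <- function(lst, species) {
  if (!is.null(lst$expr)) return(expr_propensity(lst$expr, species))
  switch(lst$type,
    mass_action = mass_action(lst$rate),
    const = const_propensity(lst$value),
    affine = affine_propensity(lst$const, counts_vector(lst$coef, species)),
    hill_repression = hill_repression(lst$K0, lst$K1, lst$H,
                                      match(lst$species, species)),
    hill_feedback = hill_feedback(lst$kfb, lst$mu,
                                  match(lst$species, species)),
    prop_feedback = proportional_feedback(lst$kfb, lst$mu,
                                          match(lst$species, species)),
    stop("unknown propensity type in config: ", lst$type))
}

#' Parse a rate expression into a custom propensity
#'
#' The expression may use the species names, arithmetic, `max()` and
#' `hill(x, K0, K1, H) = K0/(K1 + x^H)`.  Networks with expression
#' propensities are simulated with the pure-R event loop.
#'
#' @param text Expression text, e.g. `"max(5 - 0.05*O, 0) * 10"`.
#' @param species Species name vector.
#' @export
expr_propensity <- function(text, species) {
  ex <- parse(text = text)[[1]]
  fn <- function(state) {
    env <- as.list(stats::setNames(state, species))
    env$hill <- function(x, K0, K1, H) K0 / (K1 + x^H)
    eval(ex, envir = env, enclos = baseenv())
  }
  attr(fn, "expr_text") <- text
  custom_propensity(fn)
}

network_to_list <- function(network) {
  sp <- network$species
  rx <- lapply(network$reactions, function(r) {
    out <- list()
    if (!is.null(r$name)) out$name <- r$name
    rc <- named_counts(r$reactants, sp)
    if (!is.null(rc)) out$reactants <- rc
    out$propensity <- propensity_to_list(r$propensity, sp)
    if (!is.null(r$kernel)) {
      k <- r$kernel
      out$kernel <- list(kind = k$kind,
                         partition = as.list(sp[k$partition_species]))
      dl <- named_counts(kernel_delta(k, length(sp)), sp)
      if (!is.null(dl)) out$kernel$delta <- dl
    } else {
      dc <- named_counts(r$displacement, sp)
      out$displacement <- if (is.null(dc)) list() else dc
    }
    out
  })
  list(species = as.list(sp),
       output = sp[network$output],
       state0 = as.list(network$state0),
       reactions = rx)
}

network_from_list <- function(lst) {
  sp <- unlist(lst$species)
  rx <- lapply(lst$reactions, function(r) {
    kern <- NULL
    disp <- NULL
    if (!is.null(r$kernel)) {
      idx <- match(unlist(r$kernel$partition), sp)
      delta <- counts_vector(r$kernel$delta, sp)
      kern <- switch(r$kernel$kind,
        binomial_partition = binomial_partition_kernel(idx, delta),
        strict_binary_partition = strict_binary_kernel(idx, delta),
        stop("unsupported kernel kind in config: ", r$kernel$kind))
    } else {
      disp <- counts_vector(r$displacement, sp)
    }
    reaction(reactants = counts_vector(r$reactants, sp),
             propensity = propensity_from_list(r$propensity, sp),
             displacement = disp, kernel = kern,
             name = r$name)
  })
  reaction_network(species = sp, reactions = rx, output = lst$output,
                   state0 = unlist(lst$state0))
}

#' Write / read a network config file (YAML)
#'
#' @param network A [reaction_network()].
#' @param path File path.
#' @export
write_network_yaml <- function(network, path) {
  yaml::write_yaml(network_to_list(network), path)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  network_from_list(yaml::read_yaml(path))
}
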