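## Shared fixtures, built once per test run.

.fixtures <- new.env()

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ice_333 <- function() cached("ice_333", build_ice_ih(c(3, 3, 3), seed = 42))

liquid_25 <- function() cached("liquid_25", build_liquid_box(c(25, 25, 25), seed = 42))

## one mid-sized scripted trajectory shared by several analysis tests
traj_default <- function() cached("traj_default", {
  generate_trajectory(scripted_params(seed = 101))
})

traj_labels <- function() cached("traj_labels", classify_frameset(traj_default()))

## tiny frame set: explicit coordinates, open boundaries
tiny_frame <- function(coords, names = NULL, roles = "probe", box = c(100, 100, 100),
                       times = 0) {
  n <- nrow(coords)
  atoms <- data.frame(
    name = names %||% paste0("A", seq_len(n)),
    element = substr(names %||% rep("C", n), 1, 1),
    role = rep_len(roles, n),
    mol_id = seq_len(n), resid = seq_len(n), restype = "UNK")
  frame_set(coords, atoms, box, times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
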