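# crnbistab

Detection of switch-like bistability in mass-action chemical reaction
networks with conservation laws.

Signaling motifs that act as biological switches rest in one of two stable
steady states over a range of input, with distinct up- and down-switching
thresholds (hysteresis).  Given only a network's structure — species and
reactions, from an SBML file or a plain-text reaction list — this package
searches for rate constants and concentrations at which the network has a
saddle-node bifurcation, and then confirms bistability by numerical
continuation or direct simulation.  It is aimed at systems biologists and
modelers who want to know whether a candidate mechanism *can* switch, before
any rate constant has been measured.

## Method in brief

Mass action turns the network into $\dot c = Y A \psi(c)$ with
stoichiometric matrix $S$ of rank $s$.  The $\lambda = N - s$ moiety
conservation laws $C = B^T c$ are computed as a nonnegative integer basis
of $\mathrm{Null}(S^T)$ by a vertex-search linear program (simplex method,
random search directions).  Eliminating one species per law yields an
independent system $F(\mathring c, \varepsilon, k)$ whose designated
conservation total $\varepsilon$ is the bifurcation parameter.  Because $F$
is linear in $k$, $s$ pivot rate constants $\tilde k$ can be solved in
closed form from $U \tilde k = b$ so that a steady state is guaranteed; the
remaining search minimizes the squared Jacobian determinant

$$\min\ [\det J_{\mathring c}(x)]^2, \qquad c_L \le c \le c_U,\ k_L \le k \le k_U,$$

(or, in the explicit-residual mode, $[\det J]^2 + \sum_i \dot{\mathring
c}_i^2$ over all rates) with multistart annealing plus Nelder–Mead polish.
Search thoroughness is quantified by the Bayesian stopping rule
$q(n,r) = 1 - \frac{(n+a+b-1)!\,(2n+b-r-1)!}{(2n+a+b-1)!\,(n+b-r-1)!}$
(with $a=1$, $b=5$).  Candidates with a simple zero eigenvalue are
confirmed by pseudo-arclength continuation of the equilibrium branch (two
folds bound the bistable interval) or by stiff simulation of the
dose–response curve from low and high response starts.

## Worked example

The packaged Edelstein autocatalytic network (`A -> 2A; 2A -> A;
A + B <-> C; C <-> B`) with response `[A]` and signal `C1 = [B] + [C]`:

```r
library(crnbistab)
net   <- edelstein_network()
m     <- build_crnt_matrices(net);  m
#> crnt_matrices: N = 3  M = 5  R = 6  rank(S) = 2  lambda = 1
classify_linkage(net)
#> linkage classes: 2 - uniterminal
basis <- conservation_basis(m, seed = 1);  basis
#> conservation_basis: 1 law(s)
#>   C1 = c2 + c3
sys   <- select_independent_odes(m, basis, response = "A")
solve_steady_state(sys)
#> steady_state_param: fixed k1, k3
#>   k1 = (c3*k6 + c3*k5 + c1^2*k2 - C1*k6) / (c1)
#>   k3 = (c3*k6 + c3*k5 + c3*k4 - C1*k6) / (-c1*c3 + C1*c1)
```

The reference decision vector shipped with the fixture sits on the
singular steady-state manifold, and both confirmation routes agree on the
bistable window:

```r
dv   <- edelstein_decision_vector()
vals <- decision_values(sys, dv)
saddle_node_check(sys, vals)
#> saddle_node_report: saddle_node
#>   eigenvalues: -1.413e-01,  9.946e-09
continue_branch(sys, vals, eps_range = c(7.0, 8.6))
#> bifurcation_diagram: 34 points, 2 fold(s)
#>   bistable signal interval: [7.77834, 7.79489]
dr <- direct_simulation(sys, vals,
                        signal_grid = seq(7.5, 8.1, length.out = 41),
                        response_init = c(0.5, 2.0), t_max = 65000)
detect_hysteresis(dr)
#> hysteresis_report: bistable; switching thresholds 7.7775 (up from low
#> start) / 7.7925 (down from high start)
```

The two folds of the continued branch (7.778 and 7.795) and the switching
thresholds of the simulated dose–response curve agree to within the grid
spacing — the system switches up from the `[A] ≈ 1.7` branch to the
`[A] ≈ 1.0` branch at a smaller total than it switches back, the
fingerprint of a robust bistable switch.  A fresh search
(`run_search(search_config(sys, "eq5", n_starts = 50, seed = 1,
conc_bounds = c(0.001, 100), rate_bounds = c(0.001, 100)), sys,
solve_steady_state(sys))`) finds its own singular point with objective
below 1e-12 and reports `q = 1`.

The biterminal futile-cycle and prion/double-phosphorylation motifs ship
as fixtures too (`futile_cycle_network()`, `prion_network()`), each with a
reference decision vector.

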