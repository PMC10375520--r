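# shiftmaps

Chemical-shift-dependent interaction maps for NMR crystallography.

## What this is for

Assigned experimental ¹H/¹³C chemical shifts carry rich information about
how a molecule packs in the solid state, but exploiting them normally
requires quantum chemical shift calculations for every candidate crystal
structure. `shiftmaps` takes a statistical route: given a database of
crystal structures whose ¹H and ¹³C sites carry predicted shifts (with
uncertainties), it

1. finds database sites whose **covalent environment descriptor** — the
   labelled bond graph within *w* bonds of the site, matched by graph
   isomorphism — equals that of each assigned site (*w* starts at 6 and is
   reduced until > `min_matches` sites match);
2. selects `n` matching local environments (all atoms within 7 Å,
   periodic images included) either **at random** or **conditioned on the
   measured shift** by Gaussian sampling around δ_exp with width σ
   (0.5 ppm ¹H, 5 ppm ¹³C; bonded C–H pairs use a 2D Gaussian and the
   normalized distance d = √(((c−δ_C)/σ_C)² + ((h−δ_H)/σ_H)²));
3. rigidly aligns each environment onto a reference conformation via 3–4
   anchor atoms (Kabsch, proper rotations only) and accumulates
   per-element density maps G(r) = (1/n) Σ_envs Σ_atoms exp(−‖r−r_a‖²/2σ²)
   with σ = 0.5 Å on a 31³ grid with 12 Å sides (0.4 Å spacing) — an atom
   present at the same spot in every environment gives exactly 1;
4. forms the **SIM − IIM difference map** (|values| < 0.01 zeroed) whose
   positive regions are packing features promoted by the measured shift;
5. scores each candidate crystal by the voxelwise overlap
   s_i = Σ_elements Σ_r G_i^cand(r)·[G^SIM(r) − G^IIM(r)], averages over
   unambiguous sites and mean-centers across the candidate set to rank it.

A synthetic generator (`generate_toy_crystals()`, `make_shift_table()`,
`make_candidate_set()`) builds small formic-acid/methanol crystals —
H-bonded dimers, catemer chains, isolated molecules — with pseudo-shifts
`base + Δ·1(acceptor within 2 Å) + noise`, so the whole pipeline can be
exercised and validated with known ground truth and no external database.

## Worked example

```r
library(shiftmaps)

toy    <- generate_toy_crystals(40, seed = 11)    # synthetic database
shifts <- make_shift_table(toy$structures, seed = 12)
db     <- build_database(toy$structures, shifts)

cand <- make_candidate_set(n_decoys = 3, seed = 13)
asn  <- assignment_table(label = c("H2", "H1"), nucleus = c("H", "H"),
                         shift_ppm = c(10, 8))     # 10 ppm = H-bonded OH
anchors <- list(H2 = c("H2", "O2", "C1", "O1"),
                H1 = c("H1", "C1", "O1", "O2"))

fit <- shift_maps(db, cand$molecule, asn, anchors,
                  n_select = 30, min_matches = 10, seed = 42)
fit
#> <shift_maps> 2 site(s), n_select = 30
#>   H2     w=6 matches=48
#>   H1     w=6 matches=48
predict(fit, cand$candidates)
#>   candidate_id n_sites_used global_score normalized_score rank
#> 1   cand_dimer            2  5.440981452         4.082959    1
#> 2   cand_iso01            2 -0.002964026        -1.360986    2
#> 3   cand_iso03            2 -0.002964026        -1.360986    3
#> 4   cand_iso02            2 -0.002964026        -1.360986    4
```

The hydrogen-bonded dimer candidate ranks first with a strongly positive
normalized score: its oxygen sits exactly where the hydroxyl-proton
difference map (O channel, peak ≈ 0.24) says acceptor density is promoted
by the 10 ppm shift. The isolated decoys are shift-neutral (site scores
≈ 0) and tie below zero after mean-centering. Maps can be exported for
contour display with `write_volumetric(fit$sites$H2$diff_maps$O,
"H2_O.cube", "cube")` (Gaussian cube or MRC), and a command-line front
end for the fixture/database/map/score steps is installed at
`inst/scripts/shiftmaps`.

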