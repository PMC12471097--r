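# pepdigest

`pepdigest` simulates the gastrointestinal release of bioactive di- and
tripeptides from plant antimicrobial oligopeptides and characterizes what
comes out. It is aimed at food-chemistry and peptidomics researchers who
screen candidate peptides *in silico* before committing to in vitro
digestion experiments: which short fragments do pepsin, trypsin and
chymotrypsin liberate from a given oligopeptide, which of those fragments
carry known bioactivities (ACE inhibition, DPP-IV inhibition, antioxidative
activity, ...), which survive the proteases of gut microorganisms, and what
are their physicochemical properties?

The package ships the reference dataset it was built around: 57 plant
antimicrobial peptides with anticancer properties (APD accessions
`AP00236` ... `AP05050`), from thionins and viscotoxins to cyclotides and
lunasin.

## The model

**Digestion.** Each protease is a bond-cleavage specificity rule in the
Schechter–Berger sense: a set of P1 residues cleaved on their C-terminal
side, optionally a table of cleaved (P1, P1′) pairs, optional P1′
exclusions, and a substrate-length floor. Digestion is *simultaneous*: all
bonds matched by any enzyme in the set are cut in one exhaustive pass — no
kinetics, no missed cleavages. The default gastrointestinal set is pepsin
pH 1.3 (P1 = {F, L}), trypsin (P1 = {K, R}) and chymotrypsin with the
calibrated set P1 = {F, Y, W, L, M, N, H}; cleavage before proline is
allowed. Specificity lives in a YAML config, not in code.

**Resistance.** Released di/tripeptides are re-digested with two microbial
proteases: oligopeptidase F (no action on substrates shorter than 4
residues) and proteinase P1 / lactocepin (EC 3.4.21.96), encoded as an
explicit cleaved-pair table {PG, GL, IL, VF, PL, PK, PW, PF, QH, QL}. A
fragment is *resistant* iff both enzymes leave it intact.

**Characterization.** For any peptide `s` of length `L`:

- GRAVY `= (1/L) Σ KD(s_i)` (Kyte–Doolittle hydropathy);
- aliphatic index `= 100·(f_A + 2.9·f_V + 3.9·(f_I + f_L))` (Ikai);
- Boman index `= (1/L) Σ B(s_i)` in kcal/mol, hydrophilic-positive
  transfer free energies; `> 2.48` ⇒ high protein-binding potential;
- instability index `= (10/L) Σ_{i<L} DIWV(s_i, s_{i+1})` (Guruprasad);
  `> 40` ⇒ unstable in vitro;
- net charge at pH: `Σ_bases 1/(1+10^(pH−pKa)) − Σ_acids 1/(1+10^(pKa−pH))`
  over the termini and ionizable side chains (Henderson–Hasselbalch);
- theoretical pI: the unique root of the charge curve, found by bisection;
- water solubility: `good` iff the peptide contains a charged side chain
  (D, E, K, R, H).

## Worked example

```r
library(pepdigest)

# digest one oligopeptide (Cn-AMP2 from green coconut water)
tidy(digest_sequence("TESYFVFSVGM", gi_enzymes()))
#> # A tibble: 4 × 3
#>   fragment start   end
#>   <chr>    <int> <int>
#> 1 TESY         1     4
#> 2 F            5     5
#> 3 VF           6     7
#> 4 SVGM         8    11
```

The dipeptide VF (positions 6–7) is one of the bioactive fragments; the
full pipeline finds all of them across the 57-peptide reference dataset:

```r
res <- run_pipeline()
res$metadata
#> # A tibble: 1 × 5
#>   n_peptides n_fragments n_annotated rules_hash   dataset_hash
#>        <int>       <int>       <int> <chr>        <chr>
#> 1         57          47          22 a366bb1c4b4… 17f098f91d6…
```

Of the 47 unique di/tripeptides released, 22 carry known activities. Their
physicochemical profile (here the first rows, rounded to reporting
precision):

```r
format_physchem(res$physchem_report) |> head(4)
#> # A tibble: 4 × 12
#>   sequence boman net_charge    pi instability aliphatic gravy solubility
#>   <chr>    <dbl>      <dbl> <dbl>       <dbl>     <dbl> <dbl> <chr>
#> 1 ACR       3.94        0.9  8.55      153.        33.3 -0.07 good
#> 2 AR        6.56        1   10.6         5         50   -1.35 good
#> 3 AW       -2.07        0    6.1         5         50    0.45 poor
#> 4 CAK       0.82        0.9  8.55        6.67      33.3  0.13 good
#> # ℹ 4 more variables: high_binding <lgl>, unstable <lgl>, thermostable <lgl>,
#> #   pept_transportable <lgl>
```

AR, for instance, is hydrophilic (GRAVY −1.35), carries a +1 net charge at
pH 7, has pI 10.55, and its Boman index of 6.56 kcal/mol (> 2.48) flags
high protein-binding potential; the resistance screen
(`res$resistance_report`) shows it survives both microbial proteases.
`autoplot()` on a profile draws the Boman-vs-GRAVY overview with the
high-binding threshold.

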