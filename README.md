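# sdpnet

Specificity determining positions (SDPs) from protein superfamily alignments,
by combining column-versus-subfamily mutual information with column-column
coevolution networks.

## What it does

Protein superfamilies — the motivating case is fungal glycoside hydrolase
family 28 (polygalacturonases, rhamnogalacturonases, xylogalacturonases) —
split into subfamilies with different substrate specificities. Columns of the
superfamily alignment that are conserved within subfamilies but differ
between them are candidate SDPs, yet subfamily-specific conservation can also
arise by drift. `sdpnet` implements a network filter for that problem:

1. **Scrutiny** — remove truncated sequences (< 65% of the reference length),
   sequences with unique inserts or long internal gaps, profile-score
   outliers, repeat-bearing sequences, and sequences lacking the catalytic
   residues (Asp180 and/or both Asp201 / Asp-Glu202, 1CZF numbering), in
   iterated rounds.
2. **Clustering** — accept tree clades as subfamilies only when a profile
   built from the clade scores every member strictly above every non-member
   (the 100% precision-and-recall rule), and classify new sequences against
   the resulting thresholds.
3. **CDP detection** — per-column mutual information (MI, bits) with the
   subfamily partition, tested against a label-permutation null;
   columns with `z > 3.29` are Cluster Determining Positions.
4. **MI network** — plug-in MI with a row-permutation z-score for every pair
   of columns.
5. **SDN selection** — for each MI threshold (MIT) between 3.29 and the
   largest CDP–CDP edge, score the surviving network by
   `MICS_i = (sum of node i's edge z-scores) / (N - 1)` and
   `SNS = MIT x sum(MICS)`; the Specificity Determining Network is the
   candidate with maximal SNS, significance-tested against 1000 random
   same-size node sets. Its nodes, reported in reference (e.g. PDB 1CZF)
   residue numbering, are the SDPs.
6. **Synthetic superfamilies** — a generator with planted catalytic columns,
   SDPs, coevolving column pairs, gap-rich columns and corruption fixtures,
   so every stage is testable against known ground truth.

## Worked example

```r
library(sdpnet)

gen <- generate_superfamily(generator_config(seed = 7))
gen$alignment
#> aa_alignment: 180 sequences x 250 columns

run <- run_sdn_pipeline(gen$alignment, "REF", partition = gen$partition,
                        scrutinize_first = FALSE, seed = 1)
sdn <- run$analyses$all_clusters$sdn
sdn
#> sdn: 12 nodes, 59 edges, MIT = 50.91, SNS = 35510.7
#>   ensemble: z = 15.42 over 1000 random networks

sort(sdn$nodes$resnum)
#>  [1]  15  21  57  65 114 130 158 165 183 204 206 229
```

The pipeline detected 20 CDPs (the 12 planted SDP columns plus the 8 planted
coevolving columns) and the MIT scan selected the 12-column SDP clique as the
SDN: precision and recall against the planted truth (`gen$truth$sdp_cols`)
are both 1.0, and the network's SNS sits about 15 standard deviations above
random same-size node sets. Node positions are reported as residue numbers of
the designated reference sequence `REF`.

A thin shell wrapper for the same stages (simulate / scrutinize / run) is
installed at `inst/scripts/sdn-pipeline.R`.

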