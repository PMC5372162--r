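# Fixture transcription notes

The packaged survey (`colonies.csv`, `occupancy.csv`, `taxa.csv`) is a
colony-level transcription of the published assemblage-composition table of
the original field survey, joined with its stratum-size table. The source
table enumerates complete assemblages with the number of colonies carrying
each assemblage, per island, site (LI/HI), stage (adult/juvenile) and host
type (alpha/beta); colonies not listed in any assemblage row are recorded
here with empty assemblages so that stratum totals match the stratum-size
table exactly:

| stratum                | colonies |
|------------------------|----------|
| RI adults (all beta)   | 61       |
| NC adults alpha        | 48       |
| NC adults beta         | 11       |
| RI juveniles (beta)    | 56       |
| NC juveniles alpha     | 40       |
| NC juveniles beta      | 18       |
| total                  | 234      |

Colony identities and sizes are not recoverable from the source table;
`colony_id` values are synthetic (`<region>-<site>-<A|J>-<a|b>-<nn>`) and
`L_cm`/`l_cm` are blank.

## Abundance convention

The source table counts colonies per assemblage, not individuals per
colony, so every listed taxon is recorded with `count = 1` (presence). All
survey statistics (richness profiles, co-occurrence, solitary counts) are
presence-based, so this convention is lossless for them.

## Ambiguous composite rows and the readings chosen

Two source rows admit more than one colony-level reading; the chosen
readings and rejected alternatives are:

1. "T. serenei + A. lottini (N = 3 juveniles)" nested under
   *T. septata* + *A. lottini* L1, NC-LI adult alpha, 1 colony.
   **Chosen:** one colony `{Tsept, AlotL1, Tser, Alot}`, where `Alot` is
   the unresolved *A. lottini* placeholder standing for the three juvenile
   shrimps that were not assigned to a lineage (recorded with count 1 under
   the presence convention; the individual count 3 is noted here only).
   **Alternative rejected:** reading the three juveniles as three separate
   colonies — this would break the stratum total of 29 NC-LI adult alpha
   colonies.
2. "A. lottini L1 (N = 1 juvenile)" nested under
   *T. cymodoce* + *A. lottini* L2, NC-LI adult alpha, 1 colony.
   **Chosen:** one colony `{Tcymo, AlotL2, AlotL1}` carrying both shrimp
   lineages. **Alternative rejected:** a separate *T. cymodoce* +
   *A. lottini* L1 subgroup without L2 — this reading is contradicted by
   the stratum total and by the survey's canonical co-occurrence count of
   exactly one NC alpha adult colony hosting both *A. lottini* lineages.

Both chosen readings were verified against every stratum total and against
all canonical observed statistics of the survey (richness-profile counts,
pairwise co-occurrences, solitary counts, prevalence percentages), which
reproduce exactly under them; see `reference_counts.csv`.
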