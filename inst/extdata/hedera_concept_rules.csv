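original_name,revised_species,category,change_type,note
Hedera azorica,Hedera azorica,correct,same_concept,
Hedera canariensis,Hedera azorica,misidentification,plain_error,cascade error from the historical misuse of the epithet canariensis
Hedera helix,Hedera azorica,misidentification,plain_error,
Hedera helix var. azorica,Hedera azorica,soft_change,rank_change,Azorean ivy once treated as a variety of H. helix
Hedera helix var. canariensis,Hedera azorica,misidentification,plain_error,
Hedera helix var. hibernica,Hedera azorica,misidentification,plain_error,
Hedera canariensis,Hedera canariensis,correct,same_concept,
Hedera helix,Hedera canariensis,misidentification,plain_error,
Hedera helix var. canariensis,Hedera canariensis,soft_change,rank_change,Canarian variety raised to species rank
Hedera helix,Hedera helix,correct,same_concept,
Hedera hibernica,Hedera helix,misidentification,plain_error,
Hedera colchica,Hedera helix,misidentification,plain_error,distinct extant species applied in error
Hedera helix var. sarniensis,Hedera helix,misidentification,plain_error,
Hedera algeriensis,Hedera helix,soft_change,synonym,legacy name sunk into H. helix
Hedera arborea,Hedera helix,soft_change,synonym,legacy name sunk into H. helix
Hedera caucasica,Hedera helix,soft_change,synonym,legacy name sunk into H. helix
Hedera poetarum,Hedera helix,soft_change,synonym,legacy name sunk into H. helix
Hedera taurica,Hedera helix,soft_change,synonym,legacy name sunk into H. helix
Hedera helix var. arborea,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. burgalensis,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. floribunda,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. helix,Hedera helix,soft_change,rank_change,autonym recorded at infraspecific rank
Hedera helix var. minima,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. paniculata,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. pedunculata,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. poetarum,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. rhizomatifera,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera helix var. typica,Hedera helix,soft_change,synonym,legacy variety no longer recognised
Hedera hibernica,Hedera hibernica,correct,same_concept,
Hedera helix,Hedera hibernica,misidentification,plain_error,systematic confusion of the Atlantic ivy with the common ivy
Hedera helix var. helix,Hedera hibernica,misidentification,plain_error,
Hedera congesta,Hedera hibernica,misidentification,plain_error,
Hedera helix var. borealis,Hedera hibernica,misidentification,plain_error,
Hedera helix var. digitata,Hedera hibernica,misidentification,plain_error,
Hedera helix var. sarracena,Hedera hibernica,misidentification,plain_error,
Hedera helix var. sarniensis,Hedera hibernica,misidentification,plain_error,
Hedera canariensis,Hedera hibernica,hard_change,nomenclatural_confusion,canariensis historically applied to non-multiangulate ivies of Iberia
Hedera helix var. canariensis,Hedera hibernica,hard_change,nomenclatural_confusion,
Hedera helix var. hibernica,Hedera hibernica,soft_change,rank_change,variety raised to species rank
Hedera iberica,Hedera iberica,correct,same_concept,
Hedera helix,Hedera iberica,misidentification,plain_error,
Hedera helix var. helix,Hedera iberica,misidentification,plain_error,
Hedera helix var. rhizomatifera,Hedera iberica,misidentification,plain_error,
Hedera hibernica,Hedera iberica,misidentification,plain_error,
Hedera canariensis,Hedera iberica,hard_change,nomenclatural_confusion,canariensis historically applied to southwestern Iberian ivies
Hedera helix var. canariensis,Hedera iberica,hard_change,nomenclatural_confusion,
Hedera maderensis var. iberica,Hedera iberica,soft_change,split_allopatric,Iberian ivy raised from Madeiran subspecies to allopatric species
Hedera maderensis,Hedera maderensis,correct,same_concept,
Hedera helix,Hedera maderensis,misidentification,plain_error,
Hedera helix var. helix,Hedera maderensis,misidentification,plain_error,
Hedera canariensis,Hedera maderensis,hard_change,nomenclatural_confusion,canariensis historically applied to Madeiran ivies
Hedera helix var. canariensis,Hedera maderensis,hard_change,nomenclatural_confusion,
Hedera maderensis var. maderensis,Hedera maderensis,soft_change,rank_change,autonym recorded at infraspecific rank
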