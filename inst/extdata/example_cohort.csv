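subject_id,group,conc_nfl,conc_nfm,conc_nfh_smi35,conc_nfh_smi34,onset_site,alsfrs_baseline,alsfrs_followup,months_onset_to_baseline,months_onset_to_last_visit
S001,control,7.104448869947198e-9,3.52798947331444e-9,4.773043695017336e-8,1.657150035363235e-8,none,NA,NA,NA,NA
S002,control,1.320085735930213e-8,5.532045648807415e-9,6.071179484570933e-8,4.708991971823895e-8,none,NA,NA,NA,NA
S003,control,3.141166739385437e-8,9.544340311449872e-9,1.3887906625054479e-8,2.2432852037367546e-8,none,NA,NA,NA,NA
S004,control,2.15238671450245e-8,1.6020410500028962e-8,2.8477923511761925e-8,8.64076706480856e-8,none,NA,NA,NA,NA
S005,control,1.4983084506759678e-8,4.391996373234248e-9,2.040086002342973e-8,2.6088625064641828e-8,none,NA,NA,NA,NA
S006,control,4.801292393851968e-8,6.87462024218163e-9,2.8067372045828968e-8,4.076023396923421e-8,none,NA,NA,NA,NA
S007,control,2.4363485389559267e-8,6.424631940963175e-9,3.880501551397403e-8,3.114200974250489e-8,none,NA,NA,NA,NA
S008,control,1.7697342372450964e-8,7.861195727232233e-9,4.13288268384055e-8,5.489635387317599e-8,none,NA,NA,NA,NA
S009,ALS,4.7196854402861736e-8,4.2391246553317514e-9,1.3640045761526643e-8,6.785625758727238e-8,bulbar,38,21,4.714506059376857,10.714506059376857
S010,ALS,6.256913340462307e-8,1.746518554721578e-9,3.328560302825204e-8,1.7940905198192572e-8,bulbar,40,33,6.480495114090692,12.480495114090692
S011,ALS,9.19223451578432e-8,7.064885167703164e-9,1.7742106448594282e-8,1.3083685063703168e-8,limb,36,19,5.374449335276362,11.374449335276362
S012,ALS,7.2655896494346e-8,8.769742801361735e-9,3.4811881310455065e-8,2.002366264263907e-8,bulbar,19,9,14.568118484194173,20.568118484194173
S013,ALS,2.59832820005299e-7,1.0002615050181367e-8,5.3545699608471605e-8,2.9593768209066223e-8,bulbar,35,34,34.25904082410523,40.25904082410523
S014,ALS,3.228488629426131e-8,3.4894636712787915e-9,2.0906732809484877e-8,4.810622748530254e-8,limb,44,41,4.867738787749319,10.86773878774932
S015,ALS,1.1943822502859547e-7,3.0804292755722076e-9,4.95414329436757e-8,3.4949637157383134e-8,limb,38,33,7.405542908776921,13.405542908776921
S016,ALS,8.427455659797388e-8,5.204867536281845e-9,1.6141029668140073e-8,2.2647705410197106e-8,limb,48,48,5.1404123942700926,11.140412394270093
S017,ALS,5.816529142619049e-8,5.398662357689535e-9,2.6014234575778503e-8,3.861458162326488e-8,limb,38,33,13.017507574247194,19.017507574247194
S018,ALS,4.215093802186604e-8,6.624249609742195e-9,2.833801042381281e-8,2.4595551329262472e-8,bulbar,27,20,27.108464789331748,33.10846478933175
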