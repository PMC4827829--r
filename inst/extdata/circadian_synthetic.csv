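# Synthetic circadian-style dataset (degrees): 10 subjects, two systolic
# blood-pressure peak times per subject, one planted anti-modal outlier at
# subject 8. Generated by make_circadian_synthetic() with its defaults.
"label","u","v"
"subject1",211.853435937054,196.710462922469
"subject2",267.03456618167,278.292730035189
"subject3",247.826888159094,249.050152473621
"subject4",322.549645470356,326.002784905374
"subject5",271.755242731131,269.344875061611
"subject6",14.4982280552561,7.63570504530711
"subject7",206.877863288067,195.47788349056
"subject8",346.181988097602,180.669019706047
"subject9",289.302422796728,298.174697841697
"subject10",322.481743006573,352.616267850727
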