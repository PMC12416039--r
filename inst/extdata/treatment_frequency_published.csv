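"treatment","count"
"Sertraline",1268882
"Escitalopram",1074882
"Citalopram",931213
"Bupropion",912409
"Fluoxetine",893127
"Venlafaxine",540360
"Paroxetine",482638
"Trazodone",468852
"Duloxetine",448276
"Amitriptyline",276302
"Mirtazapine",181744
"Bupropion & Escitalopram",110282
"Sertraline & Trazodone",107508
"Bupropion & Sertraline",103866
"Bupropion & Fluoxetine",95455
"Nortriptyline",91340
"Bupropion & Citalopram",86108
"Fluoxetine & Trazodone",83578
"Escitalopram & Trazodone",82857
"Citalopram & Trazodone",82412
"Desvenlafaxine",80573
"Bupropion & Trazodone",76985
"Trazodone & Venlafaxine",68999
"Duloxetine & Trazodone",62092
"Bupropion & Venlafaxine",55449
"Doxepin",54042
"Bupropion & Duloxetine",47801
"Pramipexole",43782
"Paroxetine & Trazodone",40673
"All other treatments",1368658
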