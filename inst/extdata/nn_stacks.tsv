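stack	dH_kcal	dS_cal	source_tag
AA/TT	-7.9	-22.2	unified_wc
AT/TA	-7.2	-20.4	unified_wc
TA/AT	-7.2	-21.3	unified_wc
CA/GT	-8.5	-22.7	unified_wc
GT/CA	-8.4	-22.4	unified_wc
CT/GA	-7.8	-21.0	unified_wc
GA/CT	-8.2	-22.2	unified_wc
CG/GC	-10.6	-27.2	unified_wc
GC/CG	-9.8	-24.4	unified_wc
GG/CC	-8.0	-19.9	unified_wc
AG/TT	1.0	0.9	single_mismatch_gt
AT/TG	-2.5	-8.3	single_mismatch_gt
CG/GT	-4.1	-11.7	single_mismatch_gt
CT/GG	-2.8	-8.0	single_mismatch_gt
GG/CT	3.3	10.4	single_mismatch_gt
GG/TT	5.8	16.3	single_mismatch_gt
GT/CG	-4.4	-12.3	single_mismatch_gt
GT/TG	4.1	9.5	single_mismatch_gt
TG/AT	-0.1	-1.7	single_mismatch_gt
TG/GT	-1.4	-6.2	single_mismatch_gt
TT/AG	-1.3	-5.3	single_mismatch_gt
AA/TC	2.3	4.6	single_mismatch_ac
AC/TA	5.3	14.6	single_mismatch_ac
CA/GC	1.9	3.7	single_mismatch_ac
CC/GA	0.6	-0.6	single_mismatch_ac
GA/CC	5.2	14.2	single_mismatch_ac
GC/CA	-0.7	-3.8	single_mismatch_ac
TA/AC	3.4	8.0	single_mismatch_ac
TC/AA	7.6	20.2	single_mismatch_ac
AC/TT	0.7	0.2	single_mismatch_ct
AT/TC	-1.2	-6.2	single_mismatch_ct
CC/GT	-0.8	-4.5	single_mismatch_ct
CT/GC	-1.5	-6.1	single_mismatch_ct
GC/CT	2.3	5.4	single_mismatch_ct
GT/CC	5.2	13.5	single_mismatch_ct
TC/AT	1.2	0.7	single_mismatch_ct
TT/AC	1.0	0.7	single_mismatch_ct
AA/TG	-0.6	-2.3	single_mismatch_ga
AG/TA	-0.7	-2.3	single_mismatch_ga
CA/GG	-0.7	-2.3	single_mismatch_ga
CG/GA	-4.0	-13.2	single_mismatch_ga
GA/CG	-0.6	-1.0	single_mismatch_ga
GG/CA	0.5	3.2	single_mismatch_ga
TA/AG	0.7	0.7	single_mismatch_ga
TG/AA	3.0	7.4	single_mismatch_ga
AA/TA	1.2	1.7	single_mismatch_like
CA/GA	-0.9	-4.2	single_mismatch_like
GA/CA	-2.9	-9.8	single_mismatch_like
TA/AA	4.7	12.9	single_mismatch_like
AC/TC	0.0	-4.4	single_mismatch_like
CC/GC	-1.5	-7.2	single_mismatch_like
GC/CC	3.6	8.9	single_mismatch_like
TC/AC	6.1	16.4	single_mismatch_like
AG/TG	-3.1	-9.5	single_mismatch_like
CG/GG	-4.9	-15.3	single_mismatch_like
GG/CG	-6.0	-15.8	single_mismatch_like
TG/AG	1.6	3.6	single_mismatch_like
AT/TT	-2.7	-10.8	single_mismatch_like
CT/GT	-5.0	-15.8	single_mismatch_like
GT/CT	-2.2	-8.4	single_mismatch_like
TT/AT	0.2	-1.5	single_mismatch_like
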