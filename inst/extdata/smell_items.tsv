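item	odor
Q1	odor-01
Q2	odor-02
Q3	odor-03
Q4	odor-04
Q5	odor-05
Q6	Grape
Q7	odor-07
Q8	odor-08
Q9	odor-09
Q10	odor-10
Q11	odor-11
Q12	odor-12
Q13	odor-13
Q14	odor-14
Q15	odor-15
Q16	odor-16
Q17	odor-17
Q18	odor-18
Q19	odor-19
Q20	odor-20
Q21	Chocolate
Q22	odor-22
Q23	odor-23
Q24	odor-24
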