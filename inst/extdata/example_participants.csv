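id,age_years,sex,child_problem,pain_discomfort,vision_difficulty,va_right,va_left,near_n8,diagnosis,reference_referral
ex01,4,male,yes,NA,NA,NA,NA,NA,allergic_conjunctivitis,refer
ex02,5,female,no,NA,NA,NA,NA,NA,normal,no_refer
ex03,27,female,NA,no,no,6/6,6/9,NA,normal,no_refer
ex04,33,male,NA,yes,no,6/6,6/6,NA,other_conjunctivitis,refer
ex05,48,female,NA,no,yes,6/18,6/12,pass,refractive_error,refer
ex06,52,male,NA,no,no,6/9,6/6,fail,presbyopia,refer
ex07,61,female,NA,no,no,6/12,6/12,pass,normal,no_refer
ex08,70,male,NA,no,yes,6/60,3/60,fail,cataract,refer
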