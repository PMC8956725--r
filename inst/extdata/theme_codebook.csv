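code,description,example_gloss
IF-PD,Inferiority feelings about physical defects,Never praised for my appearance
IF-LA,Inferiority feelings about love and affection,Feeling inferior to a brilliant partner
IF-FB,Inferiority feelings about family background,Family environment caused inferiority since childhood
IF-P,Inferiority feelings about personality,Being sensitive brings insecurity and inferiority
IF-PE,Inferiority feelings about personal experiences,A childhood spent fending for oneself
IF-SI,Inferiority feelings about social interaction,Too scared to speak to others in crowded places
IF-L,Inferiority feelings about learning,Too inferior to look at the teacher in class
IF-A,Inferiority feelings about abilities,Feeling shy and useless compared with others
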