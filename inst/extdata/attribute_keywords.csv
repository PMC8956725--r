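group,token,token_ascii,gloss,role
A1,认为,renwei,think,head
A1,以为,yiwei,feel,synonym
A2,自己,ziji,oneself,head
A2,本人,benren,myself,synonym
A2,我,wo,I,synonym
A3,不如,buru,inferior to,head
A3,比不过,bibuguo,not equal to,synonym
A4,别人,bieren,other people,head
A4,他,ta_he,he,synonym
A4,她,ta_she,she,synonym
A4,他/她们,tamen,them,synonym
A5,低落,diluo,feel low,head
A5,沮丧,jusang,depressed,synonym
A5,颓唐,tuitang,dejected,synonym
A5,萎靡,weimi,downhearted,synonym
A5,消沉,xiaochen,despondent,synonym
A6,悲伤,beishang,sadness,head
A6,心酸,xinsuan,feel sad,synonym
A6,悲戚,beiqi,grief,synonym
A6,伤感,shanggan,unhappiness,synonym
A6,悲哀,beiai,sadness,synonym
A6,哀痛,aitong,mourning,synonym
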