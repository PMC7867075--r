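day,subject,stage,epochs
2,1,WAKE,33
2,2,WAKE,74
2,3,WAKE,95
2,4,WAKE,53
2,5,WAKE,31
2,6,WAKE,52
2,7,WAKE,32
2,8,WAKE,74
2,1,REM,123
2,2,REM,99
2,3,REM,85
2,4,REM,95
2,5,REM,101
2,6,REM,135
2,7,REM,108
2,8,REM,137
2,1,LIGHT,653
2,2,LIGHT,515
2,3,LIGHT,471
2,4,LIGHT,488
2,5,LIGHT,537
2,6,LIGHT,597
2,7,LIGHT,443
2,8,LIGHT,575
2,1,DEEP,119
2,2,DEEP,206
2,3,DEEP,175
2,4,DEEP,184
2,5,DEEP,141
2,6,DEEP,140
2,7,DEEP,157
2,8,DEEP,170
3,1,WAKE,32
3,2,WAKE,60
3,3,WAKE,85
3,4,WAKE,65
3,5,WAKE,21
3,6,WAKE,57
3,7,WAKE,38
3,8,WAKE,33
3,1,REM,121
3,2,REM,102
3,3,REM,4
3,4,REM,63
3,5,REM,141
3,6,REM,156
3,7,REM,161
3,8,REM,123
3,1,LIGHT,597
3,2,LIGHT,421
3,3,LIGHT,581
3,4,LIGHT,472
3,5,LIGHT,517
3,6,LIGHT,562
3,7,LIGHT,528
3,8,LIGHT,653
3,1,DEEP,150
3,2,DEEP,197
3,3,DEEP,98
3,4,DEEP,138
3,5,DEEP,129
3,6,DEEP,279
3,7,DEEP,171
3,8,DEEP,119
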